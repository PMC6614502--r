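#' Pipeline configuration
#'
#' Bundles every tunable threshold of the analysis with its default: the
#' blank-ratio 9, the 90% coverage fraction and the 20% QC-RSD bound of the
#' clean-up conditions, the 0.05 FDR significance level, the QC-SVRC grid
#' resolutions, the permutation count and seed of the guided-PCA test, and
#' the clustering cut. A `simulate` block (a [simulation_config()]) is used
#' when no input peak table is given.
#'
#' @param paths list: `peak_table`, `sequence`, `detection` (optional input
#'   files) and `out_dir`.
#' @param thresholds list: `blank_ratio` (9), `coverage` (0.90), `qc_rsd`
#'   (20), `fdr_alpha` (0.05).
#' @param svrc list: `j` reference samples per cycle (1), grid sizes
#'   `n_eps` (8) and `n_gamma` (26).
#' @param gpca list: permutations `m` (1000) and `seed`.
#' @param clustering list: `k` (2) and `linkage` ("average").
#' @param simulate a [simulation_config()] used when no input paths are
#'   set.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(
    paths = list(peak_table = NULL, sequence = NULL, detection = NULL,
                 out_dir = tempfile("blankqc_run_")),
    thresholds = list(blank_ratio = 9, coverage = 0.90, qc_rsd = 20,
                      fdr_alpha = 0.05),
    svrc = list(j = 1, n_eps = 8, n_gamma = 26),
    gpca = list(m = 1000, seed = 1L),
    clustering = list(k = 2, linkage = "average"),
    simulate = simulation_config()) {
  stopifnot(thresholds$blank_ratio > 0, thresholds$coverage > 0,
            thresholds$qc_rsd > 0, thresholds$fdr_alpha > 0,
            thresholds$fdr_alpha < 1)
  structure(list(paths = paths, thresholds = thresholds, svrc = svrc,
                 gpca = gpca, clustering = clustering, simulate = simulate),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [pipeline_config()]; keys not present keep their defaults. The
#' `simulate` block is passed to [simulation_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  merge_block <- function(name) {
    blk <- defaults[[name]]
    for (nm in names(raw[[name]])) blk[[nm]] <- raw[[name]][[nm]]
    blk
  }
  sim <- defaults$simulate
  if (!is.null(raw$simulate)) {
    args <- raw$simulate
    if (!is.null(args$n_features)) args$n_features <- unlist(args$n_features)
    sim <- do.call(simulation_config, args)
  }
  pipeline_config(paths = merge_block("paths"),
                  thresholds = merge_block("thresholds"),
                  svrc = merge_block("svrc"),
                  gpca = merge_block("gpca"),
                  clustering = merge_block("clustering"),
                  simulate = sim)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full conditioning-assessment pipeline
#'
#' Orchestrates every stage in order: read (or simulate) the peak table,
#' annotate the injection sequence, correct within-batch drift by QC-SVRC,
#' screen features against blanks, run the blank PCA on the non-informative
#' features, compute the conditioning curves (guided-PCA delta, permutation
#' p, significant-feature counts) for intense and mild deconditioning,
#' cluster the per-position response profiles, and re-run the delta curves
#' per cluster. All result tables are written to `out_dir` via
#' [write_results()]; stage-wise feature counts are logged.
#'
#' @param config a [pipeline_config()].
#' @param table optional `peak_table` overriding the configured input paths
#'   (and the simulation).
#' @param verbose log stage progress and counts via `message()`.
#' @return a result bundle: `list(table, corrected, fits, classification,
#'   blank_pca, curves, profiles, clustering, cluster_summaries,
#'   cluster_curves, out_dir)`.
#' @export
run_pipeline <- function(config = pipeline_config(), table = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  seed <- config$gpca$seed

  pt <- .stage("read", {
    if (!is.null(table)) {
      validate_peak_table(table)
      table
    } else if (!is.null(config$paths$peak_table)) {
      read_peak_table(config$paths$peak_table, config$paths$sequence,
                      config$paths$detection)
    } else {
      say("no input peak table: simulating batch (seed ",
          config$simulate$seed, ")")
      generate_batch(config$simulate)$table
    }
  })
  say("peak table: ", nrow(pt$features), " features x ",
      nrow(pt$injections), " injections")
  if (!any(pt$injections$sample_class == "blank")) {
    stop("pipeline stage 'screen' failed: the batch contains no blank ",
         "injections, blank-based screening is impossible", call. = FALSE)
  }

  corr <- .stage("correct", correct_batch_effects(
    pt, j = config$svrc$j, n_eps = config$svrc$n_eps,
    n_gamma = config$svrc$n_gamma))
  say("QC-SVRC: ", sum(corr$fits$corrected), "/", nrow(corr$fits),
      " features corrected")

  cls <- .stage("screen", {
    th <- config$thresholds
    cond <- clean_up_conditions(corr$table, reference = corr$reference,
                                blank_ratio = th$blank_ratio,
                                coverage = th$coverage, qc_rsd = th$qc_rsd)
    co <- suppressWarnings(classify_carryover(corr$table))
    classify_features(corr$table, cond, co)
  })
  counts <- table(cls$label)
  say("screening: ", paste(names(counts), counts, sep = "=",
                           collapse = ", "))

  bpca <- .stage("blank_pca", tryCatch(
    blank_pca(corr$table, cls), error = function(e) {
      say("blank PCA skipped: ", conditionMessage(e))
      NULL
    }))

  inform <- which(cls$label == "informative")
  if (length(inform) < 2) {
    stop("pipeline stage 'assess' failed: fewer than 2 informative ",
         "features survive screening", call. = FALSE)
  }
  informative_pt <- subset_peak_table(corr$table, features = inform)

  curves <- list()
  for (ty in c("intense", "mild")) {
    curves[[ty]] <- .stage(paste0("assess_", ty), tryCatch(
      conditioning_curve(informative_pt, type = ty, m = config$gpca$m,
                         seed = seed + match(ty, c("intense", "mild")),
                         fdr_alpha = config$thresholds$fdr_alpha),
      error = function(e) {
        say("conditioning curve (", ty, ") skipped: ",
            conditionMessage(e))
        NULL
      }))
  }

  prof <- .stage("profiles", build_profiles(informative_pt,
                                            type = "intense"))
  clus <- .stage("cluster", hca_pearson(
    prof, k = config$clustering$k, linkage = config$clustering$linkage,
    rt = informative_pt$features$rt_median))
  summ <- .stage("cluster_summary",
                 cluster_summary(clus$labels, informative_pt$features, prof))
  say("clustering: ", paste(summ$summary$cluster, summ$summary$n,
                            sep = "=", collapse = ", "))

  cluster_curves <- list()
  for (cl in summ$summary$cluster) {
    sel <- which(clus$labels == cl)
    if (length(sel) < 2) next
    sub <- subset_peak_table(informative_pt, features = sel)
    cluster_curves[[paste0("cluster", cl)]] <- tryCatch(
      conditioning_curve(sub, type = "intense", m = config$gpca$m,
                         seed = seed + 10L + cl,
                         fdr_alpha = config$thresholds$fdr_alpha),
      error = function(e) NULL)
  }

  out_dir <- config$paths$out_dir
  .stage("write", {
    tabs <- list(classification = cls, svrc_fits = corr$fits,
                 cluster_labels = data.frame(
                   feature_id = informative_pt$features$feature_id,
                   cluster = clus$labels),
                 cluster_summary = summ$summary)
    for (ty in names(curves)) {
      if (!is.null(curves[[ty]])) {
        tabs[[paste0("conditioning_curve_", ty)]] <- curves[[ty]]$curve
      }
    }
    for (nm in names(cluster_curves)) {
      if (!is.null(cluster_curves[[nm]])) {
        tabs[[paste0("conditioning_curve_", nm)]] <- cluster_curves[[nm]]$curve
      }
    }
    # fingerprint the analysis parameters, not the output location
    write_results(tabs, out_dir,
                  config = config[setdiff(names(config), "paths")],
                  seed = seed)
  })
  say("results written to ", out_dir)

  list(table = pt, corrected = corr$table, fits = corr$fits,
       classification = cls, blank_pca = bpca, curves = curves,
       profiles = prof, clustering = clus, cluster_summaries = summ,
       cluster_curves = cluster_curves, out_dir = out_dir)
}
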