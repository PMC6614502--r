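#' Per-position mean intensity profiles
#'
#' For each feature, the mean corrected peak area at every relative position
#' within a deconditioning/conditioning cycle — the blank positions followed
#' by sample positions 1..8 — averaged over all cycles of the requested
#' type. Profiles are row-wise z-scored for display and clustering; features
#' whose profile is constant carry no shape information and are flagged and
#' excluded from clustering.
#'
#' @param pt a corrected `peak_table`, usually restricted to informative
#'   features.
#' @param type `"intense"` (3-blank cycles) or `"mild"` (1-blank cycles).
#' @return `list(profile, normalized, positions, constant)`: the raw and
#'   z-scored features x positions matrices, position labels (`"B1"`..,
#'   `"S1"`..`"S8"`), and the logical constant-row flag.
#' @export
build_profiles <- function(pt, type = c("intense", "mild")) {
  type <- match.arg(type)
  gsz <- if (type == "intense") 3L else 1L
  inj <- pt$injections
  in_type <- !is.na(inj$blank_group_size) & inj$blank_group_size == gsz
  if (length(unique(inj$cycle_id[in_type])) < 2) {
    stop("at least 2 ", type, " cycles are required")
  }
  n_samp <- max(inj$position_after_blank[in_type &
                                           inj$sample_class == "sample"],
                na.rm = TRUE)
  labels <- c(paste0("B", seq_len(gsz)), paste0("S", seq_len(n_samp)))
  cols <- lapply(seq_along(labels), function(i) {
    if (i <= gsz) {
      which(in_type & inj$sample_class == "blank" &
              inj$position_after_blank == i)
    } else {
      which(in_type & inj$sample_class == "sample" &
              inj$position_after_blank == i - gsz)
    }
  })
  prof <- vapply(cols, function(ix) rowMeans(pt$area[, ix, drop = FALSE]),
                 numeric(nrow(pt$features)))
  prof <- matrix(prof, nrow = nrow(pt$features),
                 dimnames = list(pt$features$feature_id, labels))
  sds <- apply(prof, 1, stats::sd)
  constant <- sds == 0
  norm <- prof
  norm[!constant, ] <- (prof[!constant, , drop = FALSE] -
                          rowMeans(prof[!constant, , drop = FALSE])) /
    sds[!constant]
  norm[constant, ] <- 0
  list(profile = prof, normalized = norm, positions = labels,
       constant = constant)
}

#' Hierarchical clustering of intensity profiles with Pearson distance
#'
#' Agglomerative clustering of per-position profiles using
#' `d = 1 - r` (Pearson correlation) as the distance, so that features with
#' the same response *shape* cluster together regardless of scale or offset.
#' The tree is cut into `k` clusters; cluster 1 is the one with more
#' members (ties broken toward the cluster with lower mean retention time
#' when `rt` is supplied).
#'
#' @param profiles output of [build_profiles()], or a numeric features x
#'   positions matrix.
#' @param k number of clusters (default 2: the two main deconditioning
#'   response families).
#' @param linkage agglomeration method (default `"average"`).
#' @param rt optional per-feature retention times for the tie-break.
#' @return `list(labels, hclust, dist, kept)`: integer cluster labels
#'   (NA for constant profiles, which are excluded), the dendrogram, the
#'   distance object and the indices of clustered features.
#' @export
hca_pearson <- function(profiles, k = 2,
                        linkage = c("average", "complete", "single"),
                        rt = NULL) {
  linkage <- match.arg(linkage)
  if (is.list(profiles) && !is.null(profiles$profile)) {
    M <- profiles$profile
    kept <- which(!profiles$constant)
  } else {
    M <- as.matrix(profiles)
    kept <- which(apply(M, 1, stats::sd) > 0)
  }
  if (length(kept) < k) {
    stop("need at least k = ", k, " non-constant profiles, got ",
         length(kept))
  }
  d <- stats::as.dist(1 - stats::cor(t(M[kept, , drop = FALSE])))
  hc <- stats::hclust(d, method = linkage)
  cut <- stats::cutree(hc, k = k)
  # relabel so cluster 1 is the largest (tie: lower mean RT)
  sizes <- tabulate(cut, nbins = k)
  ord <- order(-sizes)
  if (!is.null(rt)) {
    mean_rt <- vapply(seq_len(k),
                      function(c) mean(rt[kept][cut == c]), numeric(1))
    ord <- order(-sizes, mean_rt)
  }
  relabel <- match(seq_len(k), ord)
  labels <- rep(NA_integer_, nrow(M))
  labels[kept] <- relabel[cut]
  names(labels) <- rownames(M)
  list(labels = labels, hclust = hc, dist = d, kept = kept)
}

#' Summarise profile clusters
#'
#' Per-cluster membership, m/z and retention-time quartiles, and the median
#' z-scored profile per position — the numbers needed to judge whether a
#' response cluster is chromatographically localised (e.g. late-eluting
#' lipophilic features) and what its deconditioning kinetics look like.
#'
#' @param labels integer cluster labels (NA = not clustered), as returned
#'   by [hca_pearson()].
#' @param features the `features` data.frame of the peak table
#'   (`feature_id`, `mz`, `rt_median`).
#' @param profiles output of [build_profiles()].
#' @return `list(summary, median_profile)`: a data.frame with one row per
#'   non-empty cluster (`cluster`, `n`, `fraction`, rt/mz quartiles) and
#'   the k x positions matrix of median normalized profiles.
#' @export
cluster_summary <- function(labels, features, profiles) {
  ks <- sort(unique(labels[!is.na(labels)]))
  n_tot <- sum(!is.na(labels))
  rows <- list()
  med <- matrix(NA_real_, length(ks), length(profiles$positions),
                dimnames = list(paste0("cluster", ks), profiles$positions))
  for (i in seq_along(ks)) {
    sel <- which(labels == ks[i])
    if (length(sel) == 0) next
    q_rt <- stats::quantile(features$rt_median[sel], c(0.25, 0.5, 0.75))
    q_mz <- stats::quantile(features$mz[sel], c(0.25, 0.5, 0.75))
    rows[[i]] <- data.frame(
      cluster = ks[i], n = length(sel), fraction = length(sel) / n_tot,
      rt_q1 = q_rt[[1]], rt_median = q_rt[[2]], rt_q3 = q_rt[[3]],
      mz_q1 = q_mz[[1]], mz_median = q_mz[[2]], mz_q3 = q_mz[[3]])
    med[i, ] <- apply(profiles$normalized[sel, , drop = FALSE], 2,
                      stats::median)
  }
  list(summary = do.call(rbind, rows), median_profile = med)
}

#' Export a dendrogram as Newick text
#'
#' @param hc an `hclust` object (e.g. from [hca_pearson()]).
#' @return a single Newick string.
#' @export
dendrogram_newick <- function(hc) {
  if (requireNamespace("ape", quietly = TRUE)) {
    return(ape::write.tree(ape::as.phylo(hc)))
  }
  # minimal recursive fallback
  lab <- hc$labels
  if (is.null(lab)) lab <- as.character(seq_along(hc$order))
  rec <- function(i) {
    if (i < 0) return(lab[-i])
    paste0("(", rec(hc$merge[i, 1]), ",", rec(hc$merge[i, 2]), "):",
           format(hc$height[i]))
  }
  paste0(rec(nrow(hc$merge)), ";")
}
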