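#' Construct a peak table object
#'
#' A `peak_table` bundles the four feature-by-injection matrices produced by
#' peak-picking software (peak area, retention time, peak width and a boolean
#' detection mask) together with per-feature metadata and the annotated
#' injection sequence. All downstream operations (drift correction, blank
#' screening, conditioning statistics, profile clustering) consume this
#' container.
#'
#' @param features data.frame with columns `feature_id` (unique, character),
#'   `mz` (mass-to-charge, Da, > 0) and `rt_median` (retention time, min,
#'   >= 0).
#' @param injections data.frame with at least `run_order` (1-based, gap-free)
#'   and `sample_class` (one of `"QC"`, `"sample"`, `"blank"`). If cycle
#'   annotations (`cycle_id`, `blank_group_size`, `position_after_blank`) are
#'   missing they are derived with [annotate_sequence()].
#' @param area,rt,width numeric matrices, features x injections. `area` is in
#'   arbitrary intensity units (>= 0); `rt` and `width` in minutes. Peak width
#'   is the difference between the end and start of the integration window.
#' @param detected logical matrix of the same shape, or `NULL` to derive it as
#'   `area > detection_threshold`. Gap-filled cells may carry a positive area
#'   with `detected = FALSE`.
#' @param detection_threshold numeric scalar used when `detected` is `NULL`.
#' @return An object of class `peak_table`: a list with elements `features`,
#'   `injections`, `area`, `rt`, `width`, `detected`.
#' @export
peak_table <- function(features, injections, area, rt, width,
                       detected = NULL, detection_threshold = 0) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  injections <- as.data.frame(injections, stringsAsFactors = FALSE)
  area <- as.matrix(area)
  rt <- as.matrix(rt)
  width <- as.matrix(width)
  if (is.null(detected)) {
    detected <- area > detection_threshold
  }
  detected <- matrix(as.logical(detected), nrow = nrow(area))
  if (!all(c("cycle_id", "blank_group_size", "position_after_blank") %in%
           names(injections))) {
    injections <- annotate_sequence(injections)
  }
  dimnames(area) <- dimnames(rt) <- dimnames(width) <- dimnames(detected) <-
    list(features$feature_id, as.character(injections$run_order))
  pt <- structure(
    list(features = features, injections = injections,
         area = area, rt = rt, width = width, detected = detected),
    class = "peak_table")
  validate_peak_table(pt)
  pt
}

#' Validate a peak table
#'
#' Checks the structural invariants of a [peak_table()]: matching matrix
#' dimensions, unique feature identifiers, positive m/z, non-negative areas
#' and non-negative widths at detected cells. Violations are reported with
#' the offending feature/injection coordinates.
#'
#' @param pt a `peak_table`.
#' @return `pt`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_peak_table <- function(pt) {
  stopifnot(inherits(pt, "peak_table"))
  f <- pt$features
  inj <- pt$injections
  need <- c("feature_id", "mz", "rt_median")
  if (!all(need %in% names(f))) {
    stop("features must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(f$feature_id)) {
    dup <- unique(f$feature_id[duplicated(f$feature_id)])
    stop("duplicate feature_id: ", paste(dup, collapse = ", "))
  }
  if (any(!is.finite(f$mz)) || any(f$mz <= 0)) {
    stop("mz must be finite and > 0 (feature row ",
         which(!is.finite(f$mz) | f$mz <= 0)[1], ")")
  }
  if (any(f$rt_median < 0)) {
    stop("rt_median must be >= 0 (feature row ", which(f$rt_median < 0)[1], ")")
  }
  dims <- list(pt$area, pt$rt, pt$width, pt$detected)
  if (!all(vapply(dims, function(m) all(dim(m) == c(nrow(f), nrow(inj))),
                  logical(1)))) {
    stop("area/rt/width/detected must all be ", nrow(f), " x ", nrow(inj),
         " matrices")
  }
  if (!all(inj$sample_class %in% c("QC", "sample", "blank"))) {
    bad <- which(!inj$sample_class %in% c("QC", "sample", "blank"))[1]
    stop("unknown sample_class '", inj$sample_class[bad],
         "' at run_order ", inj$run_order[bad])
  }
  if (!identical(inj$run_order, seq_len(nrow(inj)))) {
    stop("run_order must be 1..n, strictly increasing and gap-free")
  }
  bad <- which(pt$area < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("negative peak area at feature '", f$feature_id[bad[1, 1]],
         "', run_order ", inj$run_order[bad[1, 2]])
  }
  bad <- which(pt$detected & pt$width < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("negative peak width at detected cell: feature '",
         f$feature_id[bad[1, 1]], "', run_order ", inj$run_order[bad[1, 2]])
  }
  invisible(pt)
}

#' Annotate an injection sequence with cycle structure
#'
#' Derives, from the ordered run list, the deconditioning/conditioning cycle
#' structure of a batch: a maximal run of consecutive blanks opens a cycle,
#' the following samples are its conditioning injections. Each record gains
#' `cycle_id` (0 for the leading block before the first blank),
#' `blank_group_size` (number of consecutive blanks opening the cycle; NA for
#' cycle 0) and `position_after_blank` (for samples, 1..k counting from the
#' last blank; for blanks, the 1-based position within the blank group; NA
#' for QCs and for cycle-0 samples).
#'
#' The layouts this encodes are batches that start with a block of
#' conditioning QCs and then repeat cycles of either three consecutive blanks
#' (intense deconditioning) or a single blank (mild deconditioning), each
#' followed by eight replicate sample injections. Longer runs are annotated
#' with a warning: more than 3 consecutive blanks or more than 8 samples
#' between blanks are outside the supported designs but positions keep
#' counting 1..k.
#'
#' @param records data.frame with columns `run_order` and `sample_class`, or
#'   a character vector of classes (run order is then its ordering).
#' @return data.frame with columns `run_order`, `sample_class`, `cycle_id`,
#'   `blank_group_size`, `position_after_blank`.
#' @export
annotate_sequence <- function(records) {
  if (is.character(records) || is.factor(records)) {
    records <- data.frame(run_order = seq_along(records),
                          sample_class = as.character(records),
                          stringsAsFactors = FALSE)
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  stopifnot(all(c("run_order", "sample_class") %in% names(records)))
  records <- records[order(records$run_order), , drop = FALSE]
  if (!identical(as.integer(records$run_order), seq_len(nrow(records)))) {
    stop("run_order must be 1..n, strictly increasing and gap-free")
  }
  cls <- records$sample_class
  if (!all(cls %in% c("QC", "sample", "blank"))) {
    bad <- which(!cls %in% c("QC", "sample", "blank"))[1]
    stop("unknown sample_class '", cls[bad], "' at run_order ",
         records$run_order[bad])
  }
  n <- nrow(records)
  cycle_id <- integer(n)
  group_size <- rep(NA_integer_, n)
  pos <- rep(NA_integer_, n)
  cur_cycle <- 0L
  blank_run <- 0L   # position within the current blank group
  sample_run <- 0L  # position within the current post-blank sample run
  cycle_start <- integer(0)  # indices belonging to the current cycle
  for (i in seq_len(n)) {
    if (cls[i] == "blank") {
      if (blank_run == 0L) {  # a new blank group opens a new cycle
        cur_cycle <- cur_cycle + 1L
        cycle_start <- integer(0)
      }
      blank_run <- blank_run + 1L
      sample_run <- 0L
      cycle_id[i] <- cur_cycle
      pos[i] <- blank_run
      cycle_start <- c(cycle_start, i)
      if (blank_run == 4L) {
        warning("more than 3 consecutive blanks at run_order ",
                records$run_order[i], "; positions keep counting")
      }
    } else {
      if (blank_run > 0L) {
        # close the blank group: stamp its size on all its members
        group_size[cycle_start] <- blank_run
        blank_run <- 0L
        sample_run <- 0L
      }
      cycle_id[i] <- cur_cycle
      group_size[i] <- if (cur_cycle == 0L) NA_integer_ else
        group_size[cycle_start[1]]
      if (cls[i] == "sample" && cur_cycle > 0L) {
        sample_run <- sample_run + 1L
        pos[i] <- sample_run
        if (sample_run == 9L) {
          warning("more than 8 samples after the blank group ending before ",
                  "run_order ", records$run_order[i],
                  "; positions keep counting")
        }
      }
    }
  }
  if (blank_run > 0L) group_size[cycle_start] <- blank_run
  # propagate blank_group_size to all members of each cycle > 0
  for (cyc in unique(cycle_id[cycle_id > 0L])) {
    idx <- cycle_id == cyc
    gs <- group_size[idx]
    group_size[idx] <- gs[!is.na(gs)][1]
  }
  data.frame(run_order = as.integer(records$run_order),
             sample_class = cls,
             cycle_id = cycle_id,
             blank_group_size = group_size,
             position_after_blank = pos,
             stringsAsFactors = FALSE)
}

# full-precision numeric formatting so that write -> read round-trips
# reproduce doubles bit-exactly
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Read a peak table from delimited text files
#'
#' Two dialects are supported. Wide: one row per feature with columns
#' `feature_id`, `mz`, `rt_median`, then `area_<r>`, `rt_<r>`, `width_<r>`
#' for every run order `r`. Long: columns `feature_id`, `run_order`, `area`,
#' `rt`, `width`, one row per feature x injection. The dialect is detected
#' from the header.
#'
#' @param table_path path to the peak table (TSV by default; `sep = ","` for
#'   CSV).
#' @param sequence_path path to the injection sequence: TSV with columns
#'   `run_order` and `sample_class` in `{QC, sample, blank}`.
#' @param detection_path optional TSV of 0/1 with the same shape as the wide
#'   area block (features x injections). When absent, detection falls back to
#'   `area > detection_threshold`; this matters for the carry-over pattern
#'   rules, which are stated on pre-gap-filling detection status.
#' @param detection_threshold threshold used by the fallback rule.
#' @param sep field separator.
#' @return a validated [peak_table()].
#' @export
read_peak_table <- function(table_path, sequence_path, detection_path = NULL,
                            detection_threshold = 0, sep = "\t") {
  seq_df <- utils::read.delim(sequence_path, sep = sep,
                              stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("run_order", "sample_class") %in% names(seq_df))) {
    stop("sequence file must have columns run_order, sample_class: ",
         sequence_path)
  }
  inj <- annotate_sequence(seq_df)
  tab <- utils::read.delim(table_path, sep = sep, stringsAsFactors = FALSE,
                           comment.char = "#", check.names = FALSE)
  n_inj <- nrow(inj)
  if (all(c("run_order", "area", "rt", "width") %in% names(tab))) {
    pt <- .from_long(tab, inj, n_inj)
  } else {
    pt <- .from_wide(tab, inj, n_inj)
  }
  detected <- NULL
  if (!is.null(detection_path)) {
    det <- as.matrix(utils::read.delim(detection_path, sep = sep,
                                       comment.char = "#",
                                       check.names = FALSE))
    if (!all(dim(det) == dim(pt$area))) {
      stop("detection matrix is ", nrow(det), " x ", ncol(det),
           " but area is ", nrow(pt$area), " x ", ncol(pt$area))
    }
    detected <- det != 0
  }
  peak_table(pt$features, inj, pt$area, pt$rt, pt$width,
             detected = detected, detection_threshold = detection_threshold)
}

.num_block <- function(tab, cols, what) {
  m <- as.matrix(tab[, cols, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow = nrow(m)))) &
                   !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop("non-numeric ", what, " cell at row ", bad[1, 1], ", column '",
           cols[bad[1, 2]], "'")
    }
    m <- matrix(as.numeric(m), nrow = nrow(m), dimnames = dimnames(m))
  }
  m
}

.from_wide <- function(tab, inj, n_inj) {
  need <- c("feature_id", "mz", "rt_median")
  if (!all(need %in% names(tab))) {
    stop("wide peak table must have columns ", paste(need, collapse = ", "))
  }
  grab <- function(prefix) {
    cols <- paste0(prefix, "_", inj$run_order)
    missing <- setdiff(cols, names(tab))
    if (length(missing) > 0) {
      stop("peak table is missing column(s) ",
           paste(utils::head(missing, 3), collapse = ", "),
           " expected for ", n_inj, " injections")
    }
    .num_block(tab, cols, prefix)
  }
  list(features = tab[, need, drop = FALSE],
       area = grab("area"), rt = grab("rt"), width = grab("width"))
}

.from_long <- function(tab, inj, n_inj) {
  need <- c("feature_id", "run_order", "area", "rt", "width")
  stopifnot(all(need %in% names(tab)))
  ids <- unique(tab$feature_id)
  shape <- function(what) {
    m <- matrix(NA_real_, length(ids), n_inj,
                dimnames = list(ids, as.character(inj$run_order)))
    m[cbind(match(tab$feature_id, ids), match(tab$run_order, inj$run_order))] <-
      tab[[what]]
    if (anyNA(m)) {
      bad <- which(is.na(m), arr.ind = TRUE)
      stop("long peak table is missing ", what, " for feature '",
           ids[bad[1, 1]], "', run_order ", colnames(m)[bad[1, 2]])
    }
    m
  }
  meta <- tab[!duplicated(tab$feature_id), , drop = FALSE]
  has_meta <- all(c("mz", "rt_median") %in% names(tab))
  features <- data.frame(
    feature_id = ids,
    mz = if (has_meta) meta$mz[match(ids, meta$feature_id)] else NA_real_,
    rt_median = if (has_meta) meta$rt_median[match(ids, meta$feature_id)]
      else NA_real_,
    stringsAsFactors = FALSE)
  list(features = features,
       area = shape("area"), rt = shape("rt"), width = shape("width"))
}

#' Write a peak table to delimited text files
#'
#' Writes the wide dialect read by [read_peak_table()]. Numeric cells are
#' written with 17 significant digits so a write/read round trip reproduces
#' every double bit-exactly.
#'
#' @param pt a `peak_table`.
#' @param table_path,sequence_path,detection_path output paths;
#'   `detection_path = NULL` skips the detection matrix.
#' @param sep field separator.
#' @return invisibly, the paths written.
#' @export
write_peak_table <- function(pt, table_path, sequence_path,
                             detection_path = NULL, sep = "\t") {
  validate_peak_table(pt)
  ro <- pt$injections$run_order
  wide <- data.frame(feature_id = pt$features$feature_id,
                     mz = .fmt_num(pt$features$mz),
                     rt_median = .fmt_num(pt$features$rt_median),
                     stringsAsFactors = FALSE, check.names = FALSE)
  for (blk in c("area", "rt", "width")) {
    m <- pt[[blk]]
    for (j in seq_along(ro)) {
      wide[[paste0(blk, "_", ro[j])]] <- .fmt_num(m[, j])
    }
  }
  utils::write.table(wide, table_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  utils::write.table(pt$injections[, c("run_order", "sample_class")],
                     sequence_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  paths <- c(table_path, sequence_path)
  if (!is.null(detection_path)) {
    det <- matrix(as.integer(pt$detected), nrow = nrow(pt$detected),
                  dimnames = dimnames(pt$detected))
    utils::write.table(det, detection_path, sep = sep, quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, detection_path)
  }
  invisible(paths)
}

#' Write result tables with a run-metadata header
#'
#' Each data.frame in `tables` is written as TSV named `<name>.tsv` under
#' `out_dir`, preceded by `#`-prefixed header lines recording the package
#' version, a hash of the configuration and the seed, so that reruns are
#' auditable. Data rows are byte-identical across reruns with the same
#' configuration and seed.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @param config optional configuration list; hashed into the header.
#' @param seed optional integer seed recorded in the header.
#' @return invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir, config = NULL, seed = NULL) {
  stopifnot(is.list(tables), !is.null(names(tables)),
            all(nzchar(names(tables))))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  cfg_hash <- if (is.null(config)) "none" else
    sprintf("%08x", .djb2(paste(utils::capture.output(utils::str(config)),
                                collapse = "\n")))
  header <- c(
    paste0("# blankqc version: ",
           as.character(utils::packageVersion("blankqc"))),
    paste0("# config hash: ", cfg_hash),
    paste0("# seed: ", if (is.null(seed)) "none" else seed))
  paths <- character(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]], stringsAsFactors = FALSE)
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    con <- file(path, "w")
    writeLines(header, con)
    num <- vapply(df, is.numeric, logical(1)) &
      !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], .fmt_num)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

# small deterministic string hash (djb2), enough to fingerprint a config
.djb2 <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2^28
  h
}

#' @export
print.peak_table <- function(x, ...) {
  cls <- table(x$injections$sample_class)
  cat("peak_table: ", nrow(x$features), " features x ",
      nrow(x$injections), " injections\n", sep = "")
  cat("  classes: ", paste(names(cls), cls, sep = "=", collapse = ", "),
      "\n", sep = "")
  n_cyc <- max(x$injections$cycle_id)
  gs <- x$injections$blank_group_size[x$injections$cycle_id > 0]
  cat("  cycles: ", n_cyc, " (blank group sizes: ",
      paste(sort(unique(gs[!is.na(gs)])), collapse = ","), ")\n", sep = "")
  invisible(x)
}

# injections (column indices) by class, with cycle filters used throughout
.inj_idx <- function(pt, class = NULL, group_size = NULL) {
  inj <- pt$injections
  keep <- rep(TRUE, nrow(inj))
  if (!is.null(class)) keep <- keep & inj$sample_class %in% class
  if (!is.null(group_size)) {
    keep <- keep & !is.na(inj$blank_group_size) &
      inj$blank_group_size %in% group_size
  }
  which(keep)
}

#' Reference injections for drift correction
#'
#' The reference set is the leading QC block plus, before every blank
#' group, the last `j` sample injections: samples injected immediately
#' before a blank are the most "conditioned" injections available and serve
#' the role of QCs for within-batch effect correction.
#'
#' @param pt a `peak_table`.
#' @param j number of pre-blank samples per blank group to include
#'   (default 1).
#' @return integer vector of injection (column) indices, in run order.
#' @export
reference_injections <- function(pt, j = 1) {
  inj <- pt$injections
  ref <- which(inj$sample_class == "QC" & inj$cycle_id == 0L)
  is_blank <- inj$sample_class == "blank"
  starts <- which(is_blank & !c(FALSE, is_blank[-length(is_blank)]))
  for (b in starts) {
    before <- which(inj$sample_class == "sample" &
                      seq_len(nrow(inj)) < b)
    ref <- c(ref, utils::tail(before, j))
  }
  sort(unique(ref))
}

#' Subset a peak table by feature rows and/or injection columns
#'
#' @param pt a `peak_table`.
#' @param features integer/logical feature row selector (`NULL` = all).
#' @param injections integer/logical injection column selector.
#' @return a `peak_table` with all four matrices and the metadata subset
#'   consistently. Injection subsets keep the original `run_order` values.
#' @export
subset_peak_table <- function(pt, features = NULL, injections = NULL) {
  fi <- if (is.null(features)) seq_len(nrow(pt$features)) else features
  ii <- if (is.null(injections)) seq_len(nrow(pt$injections)) else injections
  structure(
    list(features = pt$features[fi, , drop = FALSE],
         injections = pt$injections[ii, , drop = FALSE],
         area = pt$area[fi, ii, drop = FALSE],
         rt = pt$rt[fi, ii, drop = FALSE],
         width = pt$width[fi, ii, drop = FALSE],
         detected = pt$detected[fi, ii, drop = FALSE]),
    class = "peak_table")
}
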