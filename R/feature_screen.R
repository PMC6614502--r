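#' Blank-based data clean-up conditions
#'
#' Evaluates, per feature, the three conditions an informative feature must
#' satisfy after within-batch effect correction:
#'
#' * (i) the ratio between the minimum peak area in biological samples and
#'   the maximum in blanks is strictly greater than `blank_ratio` (default
#'   9); a feature entirely absent from blanks (max blank area 0) has ratio
#'   `Inf` and passes;
#' * (ii) strictly more than `coverage` (default 90%) of the biological
#'   replicates have a peak area above `blank_ratio` times the maximum
#'   blank area;
#' * (iii) the %RSD of the corrected areas over the reference (QC)
#'   injections is strictly below `qc_rsd` (default 20).
#'
#' "Biological samples" means all `sample`-class injections; the leading QC
#' block counts toward coverage only if `include_qc = TRUE` (off by
#' default — the QCs' role here is precision, condition iii).
#'
#' @param pt a corrected `peak_table` (see [correct_batch_effects()]).
#' @param reference injection indices of the reference set used for the
#'   RSD; defaults to [reference_injections()] with `j = 1`.
#' @param blank_ratio,coverage,qc_rsd thresholds (strict inequalities).
#' @param include_qc count leading QCs as biological replicates in (i)-(ii).
#' @return data.frame: `feature_id`, `cond_i`, `cond_ii`, `cond_iii`,
#'   `blank_ratio`, `coverage_fraction`, `qc_rsd`.
#' @export
clean_up_conditions <- function(pt, reference = NULL, blank_ratio = 9,
                                coverage = 0.90, qc_rsd = 20,
                                include_qc = FALSE) {
  inj <- pt$injections
  blanks <- which(inj$sample_class == "blank")
  if (length(blanks) == 0) {
    stop("no blank injections: clean-up conditions (i)-(ii) are undefined")
  }
  samples <- which(inj$sample_class == "sample")
  if (include_qc) samples <- sort(c(samples, which(inj$sample_class == "QC")))
  if (is.null(reference)) reference <- reference_injections(pt, j = 1)
  n_feat <- nrow(pt$features)
  max_blank <- apply(pt$area[, blanks, drop = FALSE], 1, max)
  min_sample <- apply(pt$area[, samples, drop = FALSE], 1, min)
  ratio <- ifelse(max_blank == 0, Inf, min_sample / max_blank)
  cover <- rowMeans(pt$area[, samples, drop = FALSE] >
                      blank_ratio * max_blank)
  qc <- apply(pt$area[, reference, drop = FALSE], 1, function(v) {
    if (mean(v) == 0) NA_real_ else 100 * stats::sd(v) / mean(v)
  })
  data.frame(feature_id = pt$features$feature_id,
             cond_i = ratio > blank_ratio,
             cond_ii = cover > coverage,
             cond_iii = !is.na(qc) & qc < qc_rsd,
             blank_ratio = ratio,
             coverage_fraction = cover,
             qc_rsd = qc,
             stringsAsFactors = FALSE)
}

# detection pattern of one feature over one intense cycle:
# returns k in 1..3 if the carry-over +k pattern holds, else NA.
# pattern +k: detected in blanks 1..k, absent from blanks k+1..3,
# absent from post-blank samples 1..k, detected in samples k+1..8.
.cycle_pattern <- function(det_blank, det_sample) {
  n_b <- length(det_blank)
  n_s <- length(det_sample)
  for (k in 1:3) {
    if (k > n_b || k >= n_s) next
    ok <- all(det_blank[seq_len(k)]) &&
      (k == n_b || !any(det_blank[(k + 1):n_b])) &&
      !any(det_sample[seq_len(k)]) &&
      all(det_sample[(k + 1):n_s])
    if (ok) return(k)
  }
  NA_integer_
}

#' Classify column carry-over from detection patterns
#'
#' Column carry-over is material retained on the column that keeps eluting
#' over the injections following a sample run. Over an intense (3-blank)
#' cycle it leaves a sequential signature in the pre-gap-filling detection
#' status: a `+k` feature (k = 1, 2, 3) is detected in the first k blanks
#' and in post-blank samples k+1..8, and absent from the remaining blanks
#' and from the first k post-blank samples. A feature is labelled
#' `carryover+k` when the same `+k` pattern holds in at least
#' `match_fraction` of the complete intense cycles (default 1: every
#' cycle). Mild (1-blank) cycles cannot express the pattern and are
#' ignored.
#'
#' @param pt a `peak_table` with a detection mask.
#' @param match_fraction required fraction of intense cycles showing the
#'   same pattern.
#' @return character vector per feature: `"carryover+1"`, `"carryover+2"`,
#'   `"carryover+3"` or `NA`.
#' @export
classify_carryover <- function(pt, match_fraction = 1) {
  inj <- pt$injections
  intense <- setdiff(unique(inj$cycle_id[!is.na(inj$blank_group_size) &
                                           inj$blank_group_size == 3L]), 0L)
  out <- rep(NA_character_, nrow(pt$features))
  if (length(intense) == 0) {
    warning("no intense (3-blank) cycles: carry-over patterns undefined")
    return(out)
  }
  cyc_cols <- lapply(intense, function(cyc) {
    b <- which(inj$cycle_id == cyc & inj$sample_class == "blank")
    s <- which(inj$cycle_id == cyc & inj$sample_class == "sample")
    list(blanks = b[order(inj$position_after_blank[b])],
         samples = s[order(inj$position_after_blank[s])])
  })
  # only complete cycles (3 blanks + 8 samples) can express the pattern
  cyc_cols <- Filter(function(cc) length(cc$blanks) == 3 &&
                       length(cc$samples) == 8, cyc_cols)
  if (length(cyc_cols) == 0) {
    warning("no complete intense cycles: carry-over patterns undefined")
    return(out)
  }
  for (f in seq_len(nrow(pt$features))) {
    ks <- vapply(cyc_cols, function(cc) {
      .cycle_pattern(pt$detected[f, cc$blanks], pt$detected[f, cc$samples])
    }, integer(1))
    for (k in 1:3) {
      frac <- sum(ks == k, na.rm = TRUE) / length(ks)
      if (frac >= match_fraction && frac > 0) {
        out[f] <- paste0("carryover+", k)
        break
      }
    }
  }
  out
}

#' Classify features as informative, carry-over, contaminant or excluded
#'
#' Combines the clean-up conditions and the carry-over patterns into a
#' single per-feature label, with precedence:
#'
#' 1. `informative` — passes all three clean-up conditions (i) AND (ii) AND
#'    (iii), regardless of blank detections;
#' 2. `carryover+k` — a sequential carry-over pattern matched;
#' 3. `contaminant` — detected in at least one blank and one sample without
#'    the sequential pattern;
#' 4. `excluded` — everything else.
#'
#' @param pt a corrected `peak_table`.
#' @param conditions output of [clean_up_conditions()]; computed with
#'   defaults when `NULL`.
#' @param carryover output of [classify_carryover()]; computed with
#'   defaults when `NULL`.
#' @return data.frame: `feature_id`, `label`, the three condition flags and
#'   the diagnostics from [clean_up_conditions()].
#' @export
classify_features <- function(pt, conditions = NULL, carryover = NULL) {
  if (is.null(conditions)) conditions <- clean_up_conditions(pt)
  if (is.null(carryover)) {
    carryover <- tryCatch(classify_carryover(pt),
                          warning = function(w) {
                            rep(NA_character_, nrow(pt$features))
                          })
  }
  inj <- pt$injections
  blanks <- which(inj$sample_class == "blank")
  samples <- which(inj$sample_class == "sample")
  in_blank <- rowSums(pt$detected[, blanks, drop = FALSE]) > 0
  in_sample <- rowSums(pt$detected[, samples, drop = FALSE]) > 0
  informative <- conditions$cond_i & conditions$cond_ii & conditions$cond_iii
  label <- ifelse(informative, "informative",
                  ifelse(!is.na(carryover), carryover,
                         ifelse(in_blank & in_sample, "contaminant",
                                "excluded")))
  cbind(data.frame(feature_id = conditions$feature_id, label = label,
                   stringsAsFactors = FALSE),
        conditions[, setdiff(names(conditions), "feature_id")])
}
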