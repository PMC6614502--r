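#' Principal component analysis overview
#'
#' Thin SVD-based PCA used for batch overviews. Columns are mean-centered
#' (optionally autoscaled to unit variance); components come from the
#' singular value decomposition; the sign of each component is fixed so its
#' largest-magnitude loading is positive.
#'
#' @param X numeric matrix, observations (injections) x variables
#'   (features); at least 2 rows.
#' @param n_components number of components to return.
#' @param scale. autoscale columns to unit variance (default `FALSE`:
#'   centering only).
#' @return `list(scores, loadings, var_frac, center, scale)`: scores
#'   (`n x k`), loadings (`p x k`), and the fraction of total variance per
#'   component.
#' @export
pca_overview <- function(X, n_components = 2, scale. = FALSE) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  scl <- rep(1, ncol(X))
  if (scale.) {
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    Xc <- sweep(Xc, 2, scl, "/")
  }
  total <- sum(Xc^2)
  if (total == 0) stop("constant matrix: PCA undefined")
  k <- min(n_components, nrow(X) - 1, ncol(X))
  sv <- svd(Xc, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(i) {
    v <- sv$v[, i]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, "*")
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2, flip, "*")
  rownames(scores) <- rownames(X)
  rownames(loadings) <- colnames(X)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  list(scores = scores, loadings = loadings,
       var_frac = sv$d[seq_len(k)]^2 / total, center = ctr, scale = scl)
}

# centered X and the unit-column group indicator matrix used by guided PCA
.gpca_parts <- function(X, groups) {
  X <- as.matrix(X)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2) {
    stop("exactly two nonempty groups are required")
  }
  groups <- droplevels(groups)
  Xc <- sweep(X, 2, colMeans(X))
  if (sum(Xc^2) == 0) stop("zero total variance: delta undefined")
  Y <- stats::model.matrix(~ groups - 1)
  Y <- sweep(Y, 2, sqrt(colSums(Y^2)), "/")  # unit-length indicator columns
  list(Xc = Xc, Y = Y)
}

#' Guided-PCA delta statistic
#'
#' Ratio of the variance of the first guided principal component to the
#' variance of the first ordinary principal component. The guided direction
#' is the first right singular vector of `t(Y) %*% Xc`, where `Xc` is the
#' column-centered data and `Y` the samples x 2 group-indicator matrix with
#' unit-length columns; the reference direction is the first right singular
#' vector of `Xc` itself. Both variances use the n-1 denominator. Because
#' the first principal component maximises projected variance over unit
#' vectors, delta always lies in (0, 1]; values near 1 indicate that the
#' grouping (e.g. batch, or conditioning position vs reference) dominates
#' the data variance.
#'
#' @param X numeric matrix, samples x features.
#' @param groups length-`nrow(X)` labels with exactly two nonempty levels.
#' @return delta, a scalar in (0, 1].
#' @export
gpca_delta <- function(X, groups) {
  parts <- .gpca_parts(X, groups)
  v_g <- svd(crossprod(parts$Y, parts$Xc), nu = 0, nv = 1)$v[, 1]
  v_1 <- svd(parts$Xc, nu = 0, nv = 1)$v[, 1]
  stats::var(as.numeric(parts$Xc %*% v_g)) /
    stats::var(as.numeric(parts$Xc %*% v_1))
}

#' Permutation test for the guided-PCA delta statistic
#'
#' The group labels are permuted uniformly at random `m` times; a permuted
#' delta is computed for each. The one-sided p-value is the fraction of
#' permutations whose delta exceeds the observed one:
#' `p = sum(delta_hat < delta_p) / m` (strict inequality, no add-one
#' correction), so `p` has resolution `1/m` and can be exactly 0. An
#' optional conservative mode uses `(sum + 1) / (m + 1)` instead.
#'
#' @param X,groups as in [gpca_delta()].
#' @param m number of permutations (1000 in the original formulation;
#'   reduce for speed).
#' @param seed optional integer seed for the permutation stream.
#' @param conservative use the add-one correction.
#' @return `list(delta, delta_perm, p_value, m, seed)`.
#' @export
gpca_permutation <- function(X, groups, m = 1000, seed = NULL,
                             conservative = FALSE) {
  stopifnot(m >= 1)
  if (!is.null(seed)) set.seed(seed)
  delta_hat <- gpca_delta(X, groups)
  groups <- as.factor(groups)
  delta_perm <- vapply(seq_len(m), function(i) {
    gpca_delta(X, sample(groups))
  }, numeric(1))
  cnt <- sum(delta_hat < delta_perm)
  p <- if (conservative) (cnt + 1) / (m + 1) else cnt / m
  list(delta = delta_hat, delta_perm = delta_perm, p_value = p, m = m,
       seed = seed)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. Degenerate input (zero variance in both samples
#' with equal means) returns `t = 0, p = 1` instead of an error.
#'
#' @param x,y numeric vectors of length >= 2.
#' @return `list(t, df, p)`.
#' @export
welch_ttest <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment: monotone non-decreasing in rank
#' and capped at 1.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

# Welch t-tests of every matrix column between two row sets; returns raw p
.colwise_welch_p <- function(M, idx_a, idx_b) {
  vapply(seq_len(ncol(M)), function(j) {
    welch_ttest(M[idx_a, j], M[idx_b, j])$p
  }, numeric(1))
}

#' Conditioning curve: delta and significant-feature counts per position
#'
#' Quantifies system reconditioning after a blank. For each conditioning
#' position n in 1..(reference_position - 1), the conditioning set (all
#' samples injected in n-th position after a blank, pooled over cycles of
#' the requested deconditioning type) is compared pair-wise against the
#' reference set (samples injected in `reference_position`-th position):
#' the guided-PCA delta statistic with its permutation p-value on the peak
#' area matrix, and per-feature Welch t-tests on area, retention time and
#' peak width, each metric BH-adjusted separately, counting features with
#' adjusted p below `fdr_alpha`.
#'
#' The table passed in should already be drift-corrected and restricted to
#' the informative features (see [correct_batch_effects()],
#' [classify_features()]); retention time and peak width are compared
#' as-is, since drift correction never touches them.
#'
#' @param pt a `peak_table` (corrected, informative features).
#' @param type `"intense"` (3-blank cycles) or `"mild"` (1-blank cycles).
#' @param reference_position position of the reference set (default 8).
#' @param m permutations for the delta test.
#' @param seed integer seed governing all permutation draws.
#' @param fdr_alpha FDR significance threshold.
#' @return `list(curve, delta_results)`: `curve` is a data.frame with one
#'   row per position (`type`, `position_n`, `delta`, `p_value`,
#'   `n_sig_area`, `n_sig_rt`, `n_sig_width`, `n_set`, `n_ref`);
#'   `delta_results` the full permutation output per position. Positions
#'   with fewer than 2 injections in either set are skipped with a warning.
#' @export
conditioning_curve <- function(pt, type = c("intense", "mild"),
                               reference_position = 8, m = 1000,
                               seed = NULL, fdr_alpha = 0.05) {
  type <- match.arg(type)
  gsz <- if (type == "intense") 3L else 1L
  inj <- pt$injections
  sel <- inj$sample_class == "sample" & !is.na(inj$blank_group_size) &
    inj$blank_group_size == gsz
  if (length(unique(inj$cycle_id[sel])) < 2) {
    stop("at least 2 ", type, " cycles are required")
  }
  ref_idx <- which(sel & inj$position_after_blank == reference_position)
  if (length(ref_idx) < 2) {
    stop("fewer than 2 reference injections at position ",
         reference_position)
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  delta_results <- list()
  for (n in seq_len(reference_position - 1)) {
    set_idx <- which(sel & inj$position_after_blank == n)
    if (length(set_idx) < 2) {
      warning("position ", n, " has fewer than 2 injections; skipped")
      next
    }
    idx <- c(set_idx, ref_idx)
    groups <- factor(rep(c("set", "ref"), c(length(set_idx),
                                            length(ref_idx))))
    Xa <- t(pt$area[, idx, drop = FALSE])
    pr <- gpca_permutation(Xa, groups, m = m, seed = NULL)
    a_idx <- seq_along(set_idx)
    b_idx <- length(set_idx) + seq_along(ref_idx)
    counts <- vapply(c("area", "rt", "width"), function(blk) {
      M <- t(pt[[blk]][, idx, drop = FALSE])
      sum(bh_fdr(.colwise_welch_p(M, a_idx, b_idx)) < fdr_alpha)
    }, numeric(1))
    rows[[length(rows) + 1]] <- data.frame(
      type = type, position_n = n, delta = pr$delta, p_value = pr$p_value,
      n_sig_area = counts[["area"]], n_sig_rt = counts[["rt"]],
      n_sig_width = counts[["width"]], n_set = length(set_idx),
      n_ref = length(ref_idx), stringsAsFactors = FALSE)
    delta_results[[as.character(n)]] <- pr
  }
  list(curve = do.call(rbind, rows), delta_results = delta_results)
}

#' PCA of blanks on the non-informative features
#'
#' An overview of the blank injections using only the features screened out
#' as contaminant or column carry-over. Blanks injected in first position
#' after a sample run receive the carry-over material still eluting from
#' the column, so they separate from second/third-position blanks along the
#' leading components, and the separating loadings point at the carry-over
#' features.
#'
#' @param pt the full (corrected) `peak_table`.
#' @param classification output of [classify_features()].
#' @param n_components components to return.
#' @return as [pca_overview()], plus `blank_position` (the within-group
#'   position, 1..3, of each blank row) and `feature_label` (the screening
#'   label of each loading row).
#' @export
blank_pca <- function(pt, classification, n_components = 2) {
  lab <- classification$label[match(pt$features$feature_id,
                                    classification$feature_id)]
  keep_f <- which(lab %in% c("contaminant", "carryover+1", "carryover+2",
                             "carryover+3"))
  if (length(keep_f) < 2) {
    stop("need at least 2 non-informative (contaminant/carry-over) features")
  }
  blanks <- which(pt$injections$sample_class == "blank")
  if (length(blanks) < 3) stop("need at least 3 blank injections")
  X <- t(pt$area[keep_f, blanks, drop = FALSE])
  out <- pca_overview(X, n_components = n_components)
  out$blank_position <- pt$injections$position_after_blank[blanks]
  out$feature_label <- lab[keep_f]
  out
}
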