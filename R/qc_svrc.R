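#' Percent relative standard deviation
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation: the
#' standard precision measure for repeated injections.
#'
#' @param values numeric vector of length >= 2.
#' @return %RSD as a scalar; `NA` with a warning if the mean is 0.
#' @export
rsd <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (m == 0) {
    warning("mean is 0: RSD undefined")
    return(NA_real_)
  }
  100 * stats::sd(values) / m
}

# fit an RBF epsilon-SVR and return a prediction function. When every
# training point lies inside the epsilon tube libsvm returns an empty
# model (no support vectors); the solution is then the flat function -rho.
.svr_fit <- function(orders, areas, C, epsilon, gamma) {
  fit <- e1071::svm(x = matrix(orders, ncol = 1), y = areas,
                    type = "eps-regression", kernel = "radial",
                    cost = C, epsilon = epsilon, gamma = gamma,
                    scale = FALSE, fitted = FALSE)
  if (fit$tot.nSV == 0) {
    flat <- -fit$rho
    return(function(x) rep(flat, length(x)))
  }
  function(x) as.numeric(stats::predict(fit, matrix(x, ncol = 1)))
}

# leave-one-out RMSECV of an RBF epsilon-SVR at fixed hyperparameters
.loo_rmsecv <- function(orders, areas, C, epsilon, gamma) {
  n <- length(areas)
  err <- numeric(n)
  for (i in seq_len(n)) {
    pred <- .svr_fit(orders[-i], areas[-i], C, epsilon, gamma)
    err[i] <- areas[i] - pred(orders[i])
  }
  sqrt(mean(err^2))
}

#' Select QC-SVRC hyperparameters for one feature
#'
#' The support vector regression used for within-batch drift correction has
#' three structural hyperparameters: the penalty term C, the tolerance
#' threshold epsilon of the insensitive tube, and the RBF kernel width gamma.
#' C is fixed per feature at the median intensity of the reference (QC)
#' injections; epsilon and gamma are selected by grid search with
#' leave-one-out cross-validation minimising the RMSECV. The epsilon grid
#' spans 3-10% of the reference median (the expected instrumental
#' precision); the gamma grid spans `[1, 1e5]` log-uniformly. Ties in RMSECV
#' are broken toward the smaller gamma (smoother trend), then the larger
#' epsilon (flatter fit).
#'
#' @param qc_orders run orders of the reference injections (>= 4).
#' @param qc_areas peak areas at those injections (> 0).
#' @param n_eps,n_gamma grid resolutions (defaults 8 and 26).
#' @param eps_frac range of the epsilon grid as fractions of the reference
#'   median.
#' @param log10_gamma_range log10 range of the gamma grid.
#' @return `list(C, epsilon, gamma, rmsecv, constant)`; `constant = TRUE`
#'   (with `rmsecv = 0`) when all reference areas are identical, in which
#'   case the trend is the constant C and no search is run.
#' @export
select_svrc_hyperparameters <- function(qc_orders, qc_areas,
                                        n_eps = 8, n_gamma = 26,
                                        eps_frac = c(0.03, 0.10),
                                        log10_gamma_range = c(0, 5)) {
  stopifnot(length(qc_orders) == length(qc_areas))
  if (length(qc_areas) < 4) {
    stop("at least 4 reference injections are required")
  }
  if (any(qc_areas <= 0)) stop("reference areas must be positive")
  C <- stats::median(qc_areas)
  if (all(qc_areas == qc_areas[1])) {
    return(list(C = C, epsilon = eps_frac[1] * C, gamma = 1,
                rmsecv = 0, constant = TRUE))
  }
  eps_grid <- seq(eps_frac[1] * C, eps_frac[2] * C, length.out = n_eps)
  gamma_grid <- 10^seq(log10_gamma_range[1], log10_gamma_range[2],
                       length.out = n_gamma)
  best <- NULL
  for (g in gamma_grid) {       # ascending gamma: first hit wins ties
    for (e in rev(eps_grid)) {  # descending epsilon within a gamma
      r <- .loo_rmsecv(qc_orders, qc_areas, C, e, g)
      if (is.null(best) || r < best$rmsecv) {
        best <- list(C = C, epsilon = e, gamma = g, rmsecv = r,
                     constant = FALSE)
      }
    }
  }
  best
}

#' Fit the QC-SVRC intensity trend for one feature
#'
#' Trains an epsilon-insensitive support vector regression with RBF kernel
#' `k(t, t') = exp(-gamma (t - t')^2)` on the reference injections and
#' evaluates the predicted intensity trend at every requested run order.
#'
#' @param qc_orders,qc_areas reference run orders and areas.
#' @param C,epsilon,gamma hyperparameters, typically from
#'   [select_svrc_hyperparameters()].
#' @param eval_orders run orders at which to evaluate the trend (default the
#'   reference orders).
#' @return numeric vector of predicted intensities at `eval_orders`, or
#'   `NULL` if the optimizer failed (the feature is then flagged
#'   uncorrectable upstream).
#' @export
fit_svrc_trend <- function(qc_orders, qc_areas, C, epsilon, gamma,
                           eval_orders = qc_orders) {
  if (all(qc_areas == qc_areas[1])) {
    return(rep(qc_areas[1], length(eval_orders)))
  }
  pred <- tryCatch(.svr_fit(qc_orders, qc_areas, C, epsilon, gamma),
                   error = function(e) NULL)
  if (is.null(pred)) return(NULL)
  pred(eval_orders)
}

#' Within-batch effect correction by QC-SVRC
#'
#' Corrects the peak-area matrix of a batch for smooth within-batch
#' intensity drift. The reference set is the leading QC block plus the last
#' `j` sample injections of each cycle (samples injected immediately before
#' a blank play the role of QCs; see [reference_injections()]). Per feature,
#' hyperparameters are selected on the reference injections
#' ([select_svrc_hyperparameters()]), the trend is evaluated at every
#' injection, clipped below at `trend_floor_frac` times the reference
#' median, and the area is corrected multiplicatively:
#'
#' `corrected(f, i) = area(f, i) * median(reference areas of f) / trend(f, i)`
#'
#' Only the area matrix is corrected; retention time and peak width are
#' passed through untouched. Features with fewer than `min_reference`
#' positive reference areas, or for which the optimizer fails, are passed
#' through uncorrected and flagged.
#'
#' @param pt an annotated `peak_table`.
#' @param j trailing samples per cycle in the reference set.
#' @param n_eps,n_gamma hyperparameter grid resolutions; reduce for large
#'   batches (each grid node costs one leave-one-out pass).
#' @param trend_floor_frac lower clip for the trend, as a fraction of the
#'   reference median.
#' @param reference optional explicit injection (column) indices overriding
#'   the default reference rule.
#' @return `list(table, fits, trend, reference)`: the corrected
#'   `peak_table`; a data.frame of per-feature fits (`feature_id`, `C`,
#'   `epsilon`, `gamma`, `rmsecv`, `corrected` flag); the features x
#'   injections trend matrix; and the reference injection indices.
#' @export
correct_batch_effects <- function(pt, j = 1, n_eps = 8, n_gamma = 26,
                                  trend_floor_frac = 1e-6,
                                  reference = NULL) {
  validate_peak_table(pt)
  ref <- if (is.null(reference)) reference_injections(pt, j = j) else
    sort(unique(as.integer(reference)))
  if (length(ref) == 0) stop("empty reference set: cannot correct")
  orders <- pt$injections$run_order
  all_orders <- orders
  n_feat <- nrow(pt$features)
  corrected <- pt$area
  trend_m <- matrix(NA_real_, n_feat, ncol(pt$area),
                    dimnames = dimnames(pt$area))
  fits <- data.frame(feature_id = pt$features$feature_id,
                     C = NA_real_, epsilon = NA_real_, gamma = NA_real_,
                     rmsecv = NA_real_, corrected = FALSE,
                     stringsAsFactors = FALSE)
  for (f in seq_len(n_feat)) {
    qa <- pt$area[f, ref]
    ok <- qa > 0
    if (sum(ok) < 4) next  # uncorrectable: too few positive references
    qo <- orders[ref][ok]
    qa <- qa[ok]
    hp <- select_svrc_hyperparameters(qo, qa, n_eps = n_eps,
                                      n_gamma = n_gamma)
    trend <- fit_svrc_trend(qo, qa, hp$C, hp$epsilon, hp$gamma,
                            eval_orders = all_orders)
    if (is.null(trend)) next  # optimizer failure: flagged uncorrectable
    med <- stats::median(qa)
    trend <- pmax(trend, trend_floor_frac * med)
    corrected[f, ] <- pt$area[f, ] * med / trend
    trend_m[f, ] <- trend
    fits$C[f] <- hp$C
    fits$epsilon[f] <- hp$epsilon
    fits$gamma[f] <- hp$gamma
    fits$rmsecv[f] <- hp$rmsecv
    fits$corrected[f] <- TRUE
  }
  out <- pt
  out$area <- corrected
  list(table = out, fits = fits, trend = trend_m, reference = ref)
}
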