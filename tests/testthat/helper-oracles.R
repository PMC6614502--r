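# Independent oracles and fixture builders shared across the test files.
# Each oracle recomputes a quantity by the most literal route available so
# the implementation under test is checked against independent code paths.

# delta statistic by dense eigendecomposition (no svd())
oracle_delta <- function(X, groups) {
  X <- as.matrix(X)
  g <- as.factor(groups)
  Xc <- sweep(X, 2, colMeans(X))
  Y <- sapply(levels(g), function(l) as.numeric(g == l))
  Y <- sweep(Y, 2, sqrt(colSums(Y^2)), "/")
  M <- t(Y) %*% Xc
  vg <- eigen(t(M) %*% M, symmetric = TRUE)$vectors[, 1]
  v1 <- eigen(t(Xc) %*% Xc, symmetric = TRUE)$vectors[, 1]
  stats::var(as.numeric(Xc %*% vg)) / stats::var(as.numeric(Xc %*% v1))
}

# Welch t-test by direct formula evaluation
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# BH adjustment by the min-over-tail definition
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    rank_i <- which(ord == i)
    # min over all ranks j >= rank(i) of n * p_(j) / j, capped at 1
    tail_vals <- vapply(rank_i:n, function(j) n * p[ord[j]] / j, numeric(1))
    adj[i] <- min(1, min(tail_vals))
  }
  adj
}

# %RSD by naive two-pass computation
oracle_rsd <- function(x) {
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - 1))
  100 * s / m
}

# exhaustive-refit QC-SVRC hyperparameter search: literal double loop,
# collecting every grid node and applying the tie-break by sorting
oracle_svrc_select <- function(orders, areas, n_eps, n_gamma) {
  C <- stats::median(areas)
  eps_grid <- seq(0.03 * C, 0.10 * C, length.out = n_eps)
  gamma_grid <- 10^seq(0, 5, length.out = n_gamma)
  grid <- expand.grid(epsilon = eps_grid, gamma = gamma_grid)
  grid$rmsecv <- NA_real_
  for (r in seq_len(nrow(grid))) {
    errs <- numeric(length(areas))
    for (i in seq_along(areas)) {
      fit <- e1071::svm(x = matrix(orders[-i], ncol = 1), y = areas[-i],
                        type = "eps-regression", kernel = "radial",
                        cost = C, epsilon = grid$epsilon[r],
                        gamma = grid$gamma[r], scale = FALSE,
                        fitted = FALSE)
      pred <- if (fit$tot.nSV == 0) -fit$rho else
        as.numeric(stats::predict(fit, matrix(orders[i], ncol = 1)))
      errs[i] <- areas[i] - pred
    }
    grid$rmsecv[r] <- sqrt(mean(errs^2))
  }
  # smallest rmsecv; ties -> smaller gamma, then larger epsilon
  grid <- grid[order(grid$rmsecv, grid$gamma, -grid$epsilon), ]
  list(C = C, epsilon = grid$epsilon[1], gamma = grid$gamma[1],
       rmsecv = grid$rmsecv[1])
}

# plain (unadjusted) Rand index between two label vectors
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  up <- upper.tri(same_a)
  mean(same_a[up] == same_b[up])
}

# small peak table built by hand: n_feat features over a QC block and
# cycles given as a class string like "QQQQ SSSSSSSS BBB SSSSSSSS"
make_pt <- function(area, classes, mz = NULL, rt_median = NULL,
                    detected = NULL, rt = NULL, width = NULL) {
  area <- as.matrix(area)
  n_feat <- nrow(area)
  cls <- c(Q = "QC", S = "sample", B = "blank")[
    strsplit(gsub(" ", "", classes), "")[[1]]]
  stopifnot(length(cls) == ncol(area))
  features <- data.frame(
    feature_id = sprintf("F%03d", seq_len(n_feat)),
    mz = if (is.null(mz)) 100 + seq_len(n_feat) else mz,
    rt_median = if (is.null(rt_median)) seq_len(n_feat) / 2 else rt_median)
  if (is.null(rt)) rt <- matrix(rep(features$rt_median, ncol(area)), n_feat)
  if (is.null(width)) width <- matrix(0.1, n_feat, ncol(area))
  blankqc::peak_table(features, data.frame(run_order = seq_along(cls),
                                           sample_class = cls),
                      area, rt, width, detected = detected)
}

# compact simulation config for fast tests
small_sim <- function(seed = 1, ...) {
  args <- list(
    n_features = c(informative_stable = 4, informative_cluster1 = 10,
                   informative_cluster2 = 10, contaminant = 8,
                   carryover1 = 2, carryover2 = 2, carryover3 = 3),
    n_cycles_intense = 4, n_cycles_mild = 3, n_leading_qc = 6,
    seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(blankqc::simulation_config, args)
}
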