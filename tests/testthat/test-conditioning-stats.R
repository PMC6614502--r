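test_that("pca_overview matches a dense SVD oracle up to sign convention", {
  set.seed(51)
  X <- matrix(rnorm(10 * 50), 10, 50)
  out <- pca_overview(X, n_components = 3)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  for (i in 1:3) {
    expect_equal(abs(out$loadings[, i]), abs(sv$v[, i]), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(abs(out$scores[, i]), abs(sv$u[, i] * sv$d[i]),
                 tolerance = 1e-10, ignore_attr = TRUE)
    # sign convention: largest-magnitude loading is positive
    expect_gt(out$loadings[which.max(abs(out$loadings[, i])), i], 0)
  }
  expect_equal(out$var_frac, sv$d[1:3]^2 / sum(sv$d^2), tolerance = 1e-12)
})

test_that("rank-1 data put all variance on PC1 and constants are refused", {
  u <- rnorm(8)
  X <- outer(u, rnorm(12))
  out <- pca_overview(X, n_components = 2)
  expect_equal(out$var_frac[1], 1, tolerance = 1e-12)
  expect_error(pca_overview(matrix(3, 5, 4)), "constant")
})

test_that("scores reconstruct the data up to the discarded energy", {
  set.seed(52)
  X <- matrix(rnorm(9 * 20), 9, 20)
  k <- 3
  out <- pca_overview(X, n_components = k)
  Xc <- sweep(X, 2, colMeans(X))
  recon <- out$scores %*% t(out$loadings)
  sv <- svd(Xc)
  expect_equal(sum((Xc - recon)^2), sum(sv$d[-(1:k)]^2), tolerance = 1e-8)
})

test_that("delta is 1 for perfectly separated duplicate groups", {
  a <- rnorm(15)
  b <- rnorm(15)
  X <- rbind(a, a, a, b, b, b)
  g <- rep(c(1, 2), each = 3)
  expect_equal(gpca_delta(X, g), 1, tolerance = 1e-12)
})

test_that("delta matches the brute-force oracle and stays in (0, 1]", {
  set.seed(53)
  for (i in 1:25) {
    X <- matrix(rnorm(8 * 20), 8, 20)
    g <- sample(rep(c("a", "b"), 4))
    d <- gpca_delta(X, g)
    expect_equal(d, oracle_delta(X, g), tolerance = 1e-10)
    expect_gt(d, 0)
    expect_lte(d, 1)
  }
})

test_that("delta is small when PC1 is orthogonal to the group contrast", {
  # variance dominated by a direction orthogonal to the group-mean split
  set.seed(54)
  n <- 12
  g <- rep(c(0, 1), each = n / 2)
  big <- rep(c(20, -20), n / 2)     # feature 1: large, balanced within groups
  small_shift <- 0.5 * g + rnorm(n, 0, 0.1)  # feature 2: weak group split
  X <- cbind(big, small_shift, matrix(rnorm(n * 5, 0, 0.1), n))
  d <- gpca_delta(X, g)
  expect_lt(d, 0.2)
  expect_equal(d, oracle_delta(X, g), tolerance = 1e-10)
})

test_that("group validation rejects degenerate inputs", {
  X <- matrix(rnorm(12), 4, 3)
  expect_error(gpca_delta(X, rep("a", 4)), "two nonempty groups")
  expect_error(gpca_delta(matrix(1, 4, 3), rep(c("a", "b"), 2)),
               "zero total variance")
})

test_that("permutation p-value follows the counting definition", {
  set.seed(55)
  # overwhelming group effect: observed delta beats every permutation
  X <- rbind(matrix(rnorm(4 * 10, 0), 4, 10),
             matrix(rnorm(4 * 10, 50), 4, 10))
  g <- rep(c(0, 1), each = 4)
  pr <- gpca_permutation(X, g, m = 99, seed = 7)
  expect_equal(pr$p_value, 0)
  expect_length(pr$delta_perm, 99)
  # p lives on the grid {0, 1/m, ..., 1}
  expect_true(pr$p_value * 99 == round(pr$p_value * 99))
  # identical draw stream under the same seed
  pr2 <- gpca_permutation(X, g, m = 99, seed = 7)
  expect_identical(pr$delta_perm, pr2$delta_perm)
  # conservative mode applies the add-one correction
  pr3 <- gpca_permutation(X, g, m = 99, seed = 7, conservative = TRUE)
  expect_equal(pr3$p_value, 1 / 100)
})

test_that("a dominated delta yields p = 1", {
  # X almost constant within a strong non-group direction: the observed
  # labels split that direction evenly, while most permutations align
  # better with it. Construct the extreme case directly: observed delta
  # smaller than every permuted delta.
  set.seed(56)
  v <- c(1, -1, 1, -1, 1, -1, 1, -1) * 10
  X <- cbind(v, matrix(rnorm(8 * 4, 0, 0.05), 8))
  g <- rep(c(0, 1), 4)  # alternating labels orthogonal to nothing
  pr <- gpca_permutation(X, g, m = 200, seed = 8)
  d_obs <- gpca_delta(X, g)
  expect_equal(pr$p_value, mean(d_obs < pr$delta_perm))
})

test_that("welch_ttest matches direct formula evaluation", {
  out <- welch_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  out2 <- welch_ttest(c(1, 2, 3, 4), c(11, 12, 13, 14))
  expect_lt(out2$p, 1e-3)
  set.seed(57)
  for (i in 1:30) {
    x <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    got <- welch_ttest(x, y)
    want <- oracle_welch(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  # degenerate: both constant
  expect_equal(welch_ttest(c(2, 2), c(2, 2))$p, 1)
  expect_equal(welch_ttest(c(2, 2), c(3, 3))$p, 0)
})

test_that("bh_fdr matches the min-over-tail oracle and its invariants", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(58)
  for (i in 1:25) {
    p <- runif(sample(2:40, 1))^2
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_lte(sum(adj < 0.05), sum(p < 0.05))
  }
})

test_that("conditioning_curve pools positions across cycles of one type", {
  b <- generate_batch(small_sim(seed = 61, drift_amplitude = 0))
  inform <- which(b$truth$classes$class == "informative")
  pt <- subset_peak_table(b$table, features = inform)
  cc <- conditioning_curve(pt, "intense", m = 50, seed = 1)
  expect_equal(cc$curve$position_n, 1:7)
  expect_equal(unique(cc$curve$n_set), 4)  # 4 intense cycles
  expect_equal(unique(cc$curve$n_ref), 4)
  # deconditioned positions are far more perturbed than recovered ones
  expect_gt(cc$curve$delta[1], cc$curve$delta[7])
  expect_lte(cc$curve$p_value[1], 0.05)
  # counts bounded by the feature count
  expect_true(all(cc$curve$n_sig_area <= length(inform)))
  # reproducible bit-for-bit given (m, seed)
  cc2 <- conditioning_curve(pt, "intense", m = 50, seed = 1)
  expect_identical(cc$curve, cc2$curve)
})

test_that("a flat batch shows only false-positive level significance", {
  cfg <- small_sim(seed = 62, drift_amplitude = 0,
                   decondition = list(
                     cluster1 = list(p_max = 1, k = 5, max_dev = 0),
                     cluster2 = list(p_max = 3, k = 7, max_dev = 0)),
                   rt_shift_minutes = 0, width_shift_minutes = 0)
  b <- generate_batch(cfg)
  inform <- which(b$truth$classes$class == "informative")
  pt <- subset_peak_table(b$table, features = inform)
  cc <- conditioning_curve(pt, "intense", m = 100, seed = 2)
  n_feat <- length(inform)
  expect_true(all(cc$curve$n_sig_area <= 0.05 * n_feat + 2))
  expect_true(all(cc$curve$n_sig_rt <= 0.05 * n_feat + 2))
  # no systematically tiny p-values: at most one position below 0.05
  expect_lte(sum(cc$curve$p_value <= 0.05), 1)
})

test_that("blank PCA separates first-position blanks via carry-over", {
  b <- generate_batch(small_sim(seed = 63,
                                n_features = c(
                                  informative_stable = 4,
                                  informative_cluster1 = 6,
                                  informative_cluster2 = 6,
                                  contaminant = 10, carryover1 = 6,
                                  carryover2 = 0, carryover3 = 0)))
  corr_pt <- b$table  # blank structure does not need drift correction
  cls <- classify_features(corr_pt)
  bp <- blank_pca(corr_pt, cls)
  expect_equal(length(bp$blank_position), sum(
    corr_pt$injections$sample_class == "blank"))
  # silhouette of first- vs later-position blanks along PC1 (intense only)
  intense_blank <- !is.na(bp$blank_position) &
    corr_pt$injections$blank_group_size[
      corr_pt$injections$sample_class == "blank"] == 3
  s1 <- bp$scores[intense_blank & bp$blank_position == 1, 1]
  s23 <- bp$scores[intense_blank & bp$blank_position > 1, 1]
  gap <- abs(mean(s1) - mean(s23))
  spread <- max(stats::sd(s1), stats::sd(s23))
  expect_gt(gap, spread)  # separated groups: between >> within
  # carry-over +1 loadings dominate the separating component
  l_co <- abs(bp$loadings[bp$feature_label == "carryover+1", 1])
  l_ct <- abs(bp$loadings[bp$feature_label == "contaminant", 1])
  expect_gt(median(l_co), median(l_ct))
  # identical blanks: constant matrix is refused
  flat <- make_pt(matrix(5, 3, 12), "BBB SSSSSSSS B",
                  detected = matrix(TRUE, 3, 12))
  flat_cls <- data.frame(feature_id = flat$features$feature_id,
                         label = "contaminant")
  expect_error(blank_pca(flat, flat_cls), "constant")
})
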