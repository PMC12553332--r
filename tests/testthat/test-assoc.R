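# Association framework: residualization, NAM PCA, selection-aware global
# test, local coefficients, empirical FDR.

random_qt <- function(n, m, seed = 1) {
  set.seed(seed)
  residualize(matrix(rnorm(n * m), n, m,
                     dimnames = list(sprintf("s%d", 1:n),
                                     sprintf("bc%d", 1:m))))
}

test_that("residualize centers, scales, and projects out covariates", {
  set.seed(41)
  q <- matrix(rexp(8 * 20), 8, 20)
  qt <- residualize(q)
  expect_lt(max(abs(colMeans(qt))), 1e-12)
  expect_equal(apply(qt, 2, sd), rep(1, 20), tolerance = 1e-12)

  # covariate equal to a NAM column annihilates that column
  qt2 <- residualize(q, covariates = q[, 3])
  expect_lt(max(abs(qt2[, 3])), 1e-10)

  # covariate orthogonal to all centered columns changes nothing (needs
  # fewer columns than samples so an orthogonal direction exists)
  q4 <- q[, 1:4]
  qc <- sweep(q4, 2, colMeans(q4))
  ortho <- qr.Q(qr(cbind(1, qc)), complete = TRUE)[, 6]
  expect_lt(max(abs(residualize(q4, covariates = ortho) -
                      residualize(q4))), 1e-10)

  # rank-deficient design is rejected with the offending columns listed
  expect_error(residualize(q, covariates = cbind(a = q[, 1], b = 2 * q[, 1])),
               "rank-deficient.*[ab]")

  # constant covariate is collinear with the intercept
  expect_error(residualize(q, covariates = cbind(const = rep(2, 8))),
               "rank-deficient")
})

test_that("nam_pca is a deterministic signed thin SVD", {
  qt <- random_qt(7, 30)
  p <- nam_pca(qt)
  expect_lte(length(p$d), 6)  # N - 1 rank bound
  # reconstruction
  u <- sweep(p$scores, 2, p$d, "/")
  expect_lt(max(abs(u %*% diag(p$d) %*% t(p$loadings) - qt)), 1e-8)
  # sign convention: strongest loading of every component is positive
  for (j in seq_along(p$d))
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)

  # two samples: exactly one informative component
  qt2 <- residualize(matrix(rnorm(2 * 12), 2, 12))
  expect_equal(length(nam_pca(qt2)$d), 1L)

  # rank-1 matrix: single nonzero singular value, scores track the
  # generating sample vector
  v <- c(2, -1, 0.5, 1, -2.5)
  qt1 <- tcrossprod(v - mean(v), rnorm(15))
  p1 <- nam_pca(qt1)
  expect_equal(length(p1$d), 1L)
  expect_gt(abs(cor(p1$scores[, 1], v)), 1 - 1e-10)
})

test_that("cumulative R^2 matches lm on orthogonal score columns", {
  qt <- random_qt(9, 40, seed = 42)
  p <- nam_pca(qt)
  set.seed(43)
  y <- rnorm(9)
  r2 <- reDA:::cumulative_r2(p$scores, y)
  for (k in 1:4)
    expect_equal(r2[k],
                 summary(lm(y ~ p$scores[, 1:k, drop = FALSE]))$r.squared,
                 tolerance = 1e-10)
})

test_that("global test attains the permutation floor when y is a score column", {
  qt <- random_qt(10, 60, seed = 44)
  p <- nam_pca(qt)
  y <- p$scores[, 1]
  g <- global_test(p$scores, y, n_perm = 999, seed = 5)
  expect_equal(g$global_p, 1 / 1000)
  expect_identical(g$k_selected, 1L)
  expect_equal(g$r2[1], 1, tolerance = 1e-10)

  expect_error(global_test(p$scores, rep(1, 10), n_perm = 999, seed = 5),
               "no variation")
  expect_error(global_test(p$scores[1:3, ], y[1:3], n_perm = 999, seed = 5),
               "at least 4")
  expect_error(global_test(p$scores, y, n_perm = 50, seed = 5), "n_perm")
})

test_that("global p-values are calibrated under an independent phenotype", {
  qt <- random_qt(8, 50, seed = 45)
  p <- nam_pca(qt)
  set.seed(46)
  reps <- 200
  ps <- vapply(seq_len(reps), function(i) {
    global_test(p$scores, rnorm(8), n_perm = 199, seed = i)$global_p
  }, 0)
  expect_true(all(ps >= 1 / 200))
  hits <- sum(ps < 0.05)
  band <- qbinom(c(0.005, 0.995), reps, 0.05)  # generous binomial band
  expect_gte(hits, band[1])
  expect_lte(hits, band[2])
})

test_that("k_max = 1 reduces to a plain permutation test of R^2_1", {
  qt <- random_qt(9, 30, seed = 47)
  p <- nam_pca(qt)
  set.seed(48)
  y <- rnorm(9)
  g <- global_test(p$scores, y, k_max = 1, n_perm = 499, seed = 11)
  # independent plain permutation test on squared correlation with PC1,
  # replaying the same permutation stream
  r2_obs <- cor(y, p$scores[, 1])^2
  r2_null <- reDA:::with_seed(11, {
    perms <- reDA:::perm_indices(9, 499)
    vapply(seq_len(499),
           function(b) cor(y[perms[, b]], p$scores[, 1])^2, 0)
  })
  expect_equal(g$global_p, (1 + sum(r2_null >= r2_obs)) / 500)
  expect_identical(g$k_selected, 1L)
})

test_that("local coefficients match a brute-force projection oracle", {
  qt <- random_qt(5, 8, seed = 49)
  p <- nam_pca(qt)
  set.seed(50)
  y <- rnorm(5)
  for (k in 1:3) {
    coef <- local_coefficients(p, y, k)
    u <- svd(qt)$u[, seq_len(k), drop = FALSE]
    pk <- u %*% t(u)                       # explicit projector
    yc <- y - mean(y)
    oracle <- vapply(seq_len(ncol(qt)), function(i) {
      sum(yc * (pk %*% qt[, i])) / sqrt(sum(qt[, i]^2) * sum(yc^2))
    }, 0)
    expect_equal(unname(coef), oracle, tolerance = 1e-10)
    expect_true(all(abs(coef) <= 1))
  }
  expect_error(local_coefficients(p, y, k = 10), "exceeds")
})

test_that("coefficient edge cases: exact column, orthogonal column", {
  # build a NAM whose column 1 is exactly the (centered, scaled) phenotype
  set.seed(51)
  n <- 8
  y <- rnorm(n)
  q <- cbind(y, matrix(rnorm(n * 11), n, 11))
  qt <- residualize(q)
  p <- nam_pca(qt)
  coef <- local_coefficients(p, y, k = length(p$d))  # full rank retained
  expect_equal(unname(coef[1]), 1, tolerance = 1e-8)

  # a column orthogonal to the retained subspace gets 0: three copies of
  # the phenotype direction make it PC1, the orthogonal column is ignored
  # at k = 1
  yc <- y - mean(y)
  ortho <- qr.resid(qr(cbind(1, yc)), rnorm(n))
  p2 <- nam_pca(residualize(cbind(yc, yc, yc, ortho)))
  coef2 <- local_coefficients(p2, y, k = 1)
  expect_lt(abs(coef2[4]), 1e-8)

  # invariances: positive scaling of y leaves coefficients unchanged,
  # negation flips their sign
  expect_equal(local_coefficients(p, 3.7 * y, k = 2),
               local_coefficients(p, y, k = 2), tolerance = 1e-12)
  expect_equal(local_coefficients(p, -y, k = 2),
               -local_coefficients(p, y, k = 2), tolerance = 1e-12)
})

test_that("empirical FDR table is monotone, bounded, and safe at the top", {
  qt <- random_qt(10, 80, seed = 52)
  p <- nam_pca(qt)
  set.seed(53)
  y <- rnorm(10)
  g <- global_test(p$scores, y, n_perm = 199, seed = 3)
  coef <- local_coefficients(p, y, g$k_selected)
  suppressMessages(
    e <- empirical_fdr(p, y, coef, n_perm = 199, seed = 3))
  expect_true(all(diff(e$fdr_table$threshold) > 0))
  expect_true(all(e$fdr_table$fdr >= 0 & e$fdr_table$fdr <= 1))
  expect_true(all(diff(e$fdr_table$fdr) <= 0))          # non-increasing
  expect_true(max(e$fdr_table$threshold) >= max(abs(coef)) - 1e-12)
  expect_true(all(is.finite(e$fdr_table$fdr)))          # no divide-by-zero
  if (!is.na(e$t_star))
    expect_identical(e$passing, abs(coef) >= e$t_star)
  else
    expect_false(any(e$passing))
})

test_that("under the global null, few cells pass the empirical FDR", {
  qt <- random_qt(8, 60, seed = 54)
  p <- nam_pca(qt)
  set.seed(55)
  frac <- vapply(1:30, function(i) {
    y <- rnorm(8)
    g <- global_test(p$scores, y, n_perm = 199, seed = 100 + i)
    coef <- local_coefficients(p, y, g$k_selected)
    suppressMessages(
      e <- empirical_fdr(p, y, coef, n_perm = 199, seed = 100 + i))
    mean(e$passing)
  }, 0)
  expect_lte(mean(frac), 0.05)
})

test_that("association_test enforces the design preconditions", {
  # a NAM over 3 samples is constructible, but testing it is refused
  set.seed(57)
  W <- Matrix::Matrix(random_walk_matrix(30), sparse = TRUE)
  bc <- sprintf("bc%02d", 1:30)
  dimnames(W) <- list(bc, bc)
  stw <- sample_table(data.frame(barcode = bc,
                                 sample = rep(sprintf("s%02d", 1:3), 10)),
                      data.frame(sample = sprintf("s%02d", 1:3),
                                 phenotype = c(0, 1, 1)))
  nam <- nam_from_walk(rwr_walk(W, 1, 0.3), stw)
  expect_error(association_test(nam, stw, seed = 1), "at least 4")
  expect_error(association_test(nam, stw), "seed is required")
})

test_that("batch strata restrict permutations and warn on singletons", {
  expect_warning(reDA:::perm_indices(5, 100, batch = c(1, 1, 2, 2, 3)),
                 "single sample")
  set.seed(56)
  idx <- reDA:::perm_indices(6, 50, batch = c(1, 1, 1, 2, 2, 2))
  # permutations never cross batch boundaries
  expect_true(all(idx[1:3, ] %in% 1:3) && all(idx[4:6, ] %in% 4:6))
})
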