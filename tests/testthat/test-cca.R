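test_that("residualization matches the hat-matrix oracle", {
  set.seed(1)
  D <- matrix(rnorm(5 * 3), 5, 3)
  C <- matrix(rnorm(5 * 2), 5, 2)
  X <- cbind(1, C)
  H <- X %*% solve(crossprod(X), t(X))
  expect_equal(residualize(D, C), D - H %*% D, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("residualization edge cases", {
  set.seed(2)
  C <- matrix(rnorm(60), 30, 2)
  expect_lt(max(abs(residualize(C[, 1, drop = FALSE], C))), 1e-10)
  D <- matrix(rnorm(30), 30, 1)
  expect_warning(residualize(D, cbind(C, C[, 1])), "rank-deficient")
  # centering only when confounds are NULL
  expect_equal(colMeans(residualize(D, NULL)), 0, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("identical single columns give canonical correlation 1", {
  set.seed(3)
  y <- matrix(rnorm(40), 40, 1)
  m <- fit_cca(y, y)
  expect_equal(m$cor, 1, tolerance = 1e-10)
})

test_that("canonical correlations match the eigen oracle", {
  set.seed(4)
  for (rep in 1:10) {
    Y <- matrix(rnorm(50 * 5), 50, 5)
    X <- matrix(rnorm(50 * 4), 50, 4)
    X[, 1] <- X[, 1] + 0.5 * Y[, 1]
    m <- fit_cca(Y, X)
    expect_equal(m$cor, cca_eigen_oracle(Y, X), tolerance = 1e-8)
  }
})

test_that("canonical correlations are invariant to within-block transforms", {
  set.seed(5)
  Y <- matrix(rnorm(80 * 4), 80, 4)
  X <- matrix(rnorm(80 * 3), 80, 3)
  A <- matrix(rnorm(16), 4, 4) + diag(4)
  B <- matrix(rnorm(9), 3, 3) + diag(3)
  expect_equal(fit_cca(Y, X)$cor, fit_cca(Y %*% A, X %*% B)$cor,
               tolerance = 1e-9)
})

test_that("model internals are consistent", {
  set.seed(6)
  Y <- matrix(rnorm(60 * 4), 60, 4)
  X <- matrix(rnorm(60 * 3), 60, 3)
  m <- fit_cca(Y, X)
  # variates uncorrelated across pairs, unit variance
  expect_equal(stats::cor(m$U), diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(stats::cor(m$V), diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(apply(m$U, 2, stats::sd), rep(1, 3), tolerance = 1e-8,
               ignore_attr = TRUE)
  # stored loadings equal recomputed correlations
  expect_equal(m$loadings_Y, stats::cor(Y, m$U), tolerance = 1e-10)
  expect_equal(m$loadings_X, stats::cor(X, m$V), tolerance = 1e-10)
  expect_true(all(abs(m$loadings_Y) <= 1 + 1e-12))
  # U = Y_c A reproduces the stored variates
  Yc <- scale(Y, scale = FALSE)
  expect_equal(Yc %*% m$A, m$U, tolerance = 1e-8, ignore_attr = TRUE)
  # descending correlations
  expect_true(all(diff(m$cor) <= 1e-12))
})

test_that("fit_cca input validation", {
  set.seed(7)
  Y <- matrix(rnorm(20 * 3), 20, 3)
  expect_error(fit_cca(Y, matrix(rnorm(20 * 18), 20, 18)), "n > p \\+ q")
  expect_error(fit_cca(cbind(Y, Y[, 1]), matrix(rnorm(20), 20, 1)),
               "singularity")
})

test_that("permutation p-values are deterministic, monotone and never zero", {
  set.seed(8)
  Y <- matrix(rnorm(150 * 4), 150, 4)
  X <- matrix(rnorm(150 * 3), 150, 3)
  X[, 1] <- X[, 1] + Y[, 1]
  m1 <- permute_inference(fit_cca(Y, X), n_perm = 199, seed = 42)
  m2 <- permute_inference(fit_cca(Y, X), n_perm = 199, seed = 42)
  expect_identical(m1$p, m2$p)
  expect_true(all(diff(m1$p) >= 0))
  expect_true(all(m1$p > 0))
  expect_lte(m1$p[1], 0.01)  # strong planted signal
  expect_warning(permute_inference(fit_cca(Y, X), n_perm = 50, seed = 1),
                 "resolution")
})

test_that("unique model with empty covariate set equals the simple model", {
  set.seed(9)
  Y <- matrix(rnorm(100 * 3), 100, 3)
  X <- matrix(rnorm(100 * 2), 100, 2)
  simple <- permute_inference(fit_cca(residualize(Y, NULL),
                                      residualize(X, NULL)), 101, seed = 5)
  uniq <- unique_model(Y, X, matrix(nrow = 100, ncol = 0), NULL,
                       n_perm = 101, seed = 5)
  expect_equal(uniq$cor, simple$cor, tolerance = 1e-10)
  expect_identical(uniq$p, simple$p)
})

test_that("full mediation collapses the unique canonical correlation", {
  cfg <- small_cohort(11, rhos = c(0.5, 0.3), n = 2000, miss = 0)
  co <- generate_cohort(cfg)
  g <- attr(co, "truth")$latents
  pa <- pt_matrix(standardize_pa(co$pa))
  simple <- fit_cca(residualize(co$brain, NULL), residualize(pa, NULL))
  uniq <- unique_model(pt_matrix(co$brain), pa, g, NULL, n_perm = 199,
                       seed = 3)
  expect_gt(simple$cor[1], 0.4)
  # the latents mediate the whole cross-block link
  expect_lt(uniq$cor[1], 0.15)
  expect_gt(uniq$p[1], 0.05)
})

test_that("partial mediation attenuates but preserves the leading variate", {
  cfg <- small_cohort(12, rhos = c(0.4, 0.25), n = 2000, miss = 0)
  co <- generate_cohort(cfg)
  mh <- attr(co, "truth")$mh_latent
  pa <- pt_matrix(standardize_pa(co$pa))
  simple <- fit_cca(residualize(co$brain, NULL), residualize(pa, NULL))
  uniq <- unique_model(pt_matrix(co$brain), pa, mh, NULL, n_perm = 101,
                       seed = 4)
  expect_lte(uniq$cor[1], simple$cor[1] + 0.01)
  expect_gt(uniq$cor[1], 0.1)  # latent shared only partially via mh block
})

test_that("variate matching identifies itself and aligned models", {
  cfg <- small_cohort(13, rhos = c(0.4, 0.25), n = 1500, miss = 0)
  co <- generate_cohort(cfg)
  pa <- pt_matrix(standardize_pa(co$pa))
  Y <- residualize(co$brain, NULL)
  m <- fit_cca(Y, residualize(pa, NULL))
  self <- match_variates(m, m)
  expect_equal(self$cor, rep(1, nrow(self)), tolerance = 1e-10)
  expect_identical(self$variate_a, self$variate_b)

  mh <- attr(co, "truth")$mh_latent
  uniq <- unique_model(pt_matrix(co$brain), pa, mh, NULL, n_perm = 101, seed = 2)
  mm <- match_variates(m, uniq)
  expect_gt(mm$cor[mm$variate_a == 1], 0.9)

  expect_error(match_variates(m, fit_cca(Y[1:100, ], pa[1:100, ])),
               "share subjects")
})

test_that("loading test requires significant variates and pools nulls", {
  # full-size cohort: the loading test's power lives at n = 6000 with the
  # 28-variable brain block
  cfg <- cohort_config(n_subjects = 6000, canonical_rhos = c(0.25, 0.15),
                       missing_rate = 0, seed = 14)
  co <- generate_cohort(cfg)
  conf <- dummy_code(co$confounds)
  Y <- residualize(co$brain, conf)
  X <- residualize(pt_matrix(standardize_pa(co$pa)), conf)
  m <- permute_inference(fit_cca(Y, X), n_perm = 199, seed = 1)
  ls <- loading_significance(m, Y, n_perm = 199, seed = 2)
  nv <- length(ls$variates)
  expect_gt(nv, 0)
  expect_identical(ncol(ls$null), 199L * nv)
  expect_true(all(ls$p > 0 & ls$p <= 1))
  # driver variables (largest true loadings) should be detected
  top <- rownames(ls$p)[which.max(abs(ls$observed[, 1]))]
  expect_lt(ls$p[top, 1], 0.05)

  # no significant variates -> empty result
  m$p[] <- 1
  empty <- loading_significance(m, Y, n_perm = 101, seed = 3)
  expect_identical(length(empty$variates), 0L)
  expect_identical(ncol(empty$p), 0L)
})
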