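make_missing_table <- function(n = 41, subjects = 100, frac, seed = 1) {
  set.seed(seed)
  df <- as.data.frame(matrix(rnorm(subjects * n), subjects, n))
  for (j in seq_len(n)) {
    k <- round(frac[j] * subjects)
    if (k > 0) df[sample(subjects, k), j] <- NA
  }
  pheno_table(df)
}

test_that("sparse-variable exclusion uses a strict 30% rule", {
  tab <- make_missing_table(n = 3, subjects = 100, frac = c(0.31, 0.30, 0))
  res <- exclude_sparse_variables(tab)
  expect_identical(names(res$dropped), "V1")      # 31% dropped
  expect_true(all(c("V2", "V3") %in% names(res$table)))  # exactly 30% kept

  full <- make_missing_table(n = 4, subjects = 50, frac = rep(0, 4))
  expect_identical(as.data.frame(exclude_sparse_variables(full)$table),
                   as.data.frame(full))

  # questionnaire-shaped case: 10 of 41 items above threshold -> 31 retained
  fr <- c(rep(0.45, 10), rep(0.05, 31))
  tab41 <- make_missing_table(n = 41, subjects = 200, frac = fr, seed = 2)
  res41 <- exclude_sparse_variables(tab41)
  expect_length(res41$dropped, 10)
  expect_identical(ncol(res41$table), 31L)

  allbad <- make_missing_table(n = 2, subjects = 100, frac = c(0.5, 0.6))
  expect_error(exclude_sparse_variables(allbad), "all variables")
})

test_that("PMM leaves complete variables and observed entries untouched", {
  set.seed(3)
  df <- data.frame(a = rnorm(50), b = rnorm(50))
  df$b[1:10] <- NA
  pt <- pheno_table(df)
  out <- pmm_impute(pt, imputation_spec(n_iterations = 3, seed = 1))
  expect_identical(out$a, df$a)
  expect_identical(out$b[-(1:10)], df$b[-(1:10)])
  expect_false(anyNA(out$b))
})

test_that("every PMM draw is an observed donor value; averages stay in range", {
  set.seed(4)
  z <- rnorm(300)
  df <- data.frame(y = z + rnorm(300, sd = 0.5), x = z)
  mis <- sample(300, 90)
  df$y[mis] <- NA
  out <- pmm_impute(pheno_table(df), imputation_spec(n_iterations = 5, seed = 2))
  draws <- attr(out, "draws")$y
  obs <- df$y[-mis]
  expect_true(all(draws %in% obs))
  expect_true(all(out$y[mis] >= min(obs) & out$y[mis] <= max(obs)))
})

test_that("deterministic k=1 PMM matches the nearest-prediction oracle", {
  # 6-row toy with a known regression: the imputed value must be the observed
  # y whose least-squares prediction is closest to the missing row's
  toy <- data.frame(y = c(1.0, 2.1, 2.9, 4.2, 5.0, NA),
                    x = c(1, 2, 3, 4, 5, 3.4))
  fit <- stats::lm(y ~ x, data = toy[1:5, ])
  pred_obs <- stats::predict(fit, toy[1:5, ])
  pred_mis <- stats::predict(fit, toy[6, ])
  oracle <- toy$y[which.min(abs(pred_obs - pred_mis))]
  out <- pmm_impute(pheno_table(toy),
                    imputation_spec(n_iterations = 1, n_donors = 1,
                                    draw_coefficients = FALSE, seed = 1))
  expect_identical(out$y[6], oracle)
})

test_that("rank-deficient predictors are dropped with a warning", {
  set.seed(5)
  df <- data.frame(y = rnorm(40), x1 = rnorm(40))
  df$x2 <- df$x1  # collinear
  df$y[1:8] <- NA
  expect_warning(
    pmm_impute(pheno_table(df), imputation_spec(n_iterations = 1, seed = 1)),
    "rank-deficient")
})

test_that("categorical imputation honours structure and degenerate levels", {
  set.seed(6)
  n <- 400
  x <- rnorm(n)
  g <- factor(ifelse(x > 0, "hi", "lo"))
  df <- data.frame(g = g, x = x)
  truth <- df$g
  df$g[1:80] <- NA
  pt <- pheno_table(df, c(g = "categorical", x = "continuous"))
  out <- categorical_impute(pt, imputation_spec(n_iterations = 5, seed = 1))
  expect_gt(mean(out$g[1:80] == truth[1:80]), 0.9)

  # single observed level: everything imputed to that level
  df2 <- data.frame(g = factor(rep("only", 30), levels = c("only", "ghost")),
                    x = rnorm(30))
  df2$g[1:5] <- NA
  pt2 <- pheno_table(df2, c(g = "categorical", x = "continuous"))
  out2 <- categorical_impute(pt2, imputation_spec(n_iterations = 3, seed = 1))
  expect_true(all(out2$g[1:5] == "only"))
})

test_that("dummy coding produces m-1 reference-coded indicators", {
  df <- data.frame(site = factor(c("s1", "s2", "s3", "s1")),
                   sex = factor(c("f", "m", "f", "m")),
                   x = 1:4)
  pt <- pheno_table(df, c(site = "categorical", sex = "categorical",
                          x = "continuous"))
  dc <- dummy_code(pt)
  expect_identical(names(dc), c("site_s2", "site_s3", "sex_m", "x"))
  expect_true(all(rowSums(as.data.frame(dc)[c("site_s2", "site_s3")]) <= 1))
  df$x[1] <- NA
  expect_error(dummy_code(pheno_table(df, var_kinds(pt))), "impute")
})
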