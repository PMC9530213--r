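test_that("population canonical correlations equal the planted values exactly", {
  cfg <- cohort_config(n_subjects = 100, canonical_rhos = c(0.25, 0.15), seed = 1)
  for (block in c("pa", "mh")) {
    rho <- population_canonical_correlations(cfg, block)
    expect_equal(rho[1:2], c(0.25, 0.15), tolerance = 1e-10)
    expect_true(all(abs(rho[-(1:2)]) < 1e-10))
  }
})

test_that("population canonicals match a Monte-Carlo CCA oracle", {
  cfg <- cohort_config(n_subjects = 200000, canonical_rhos = c(0.3, 0.12),
                       n_brain_edges = 4, n_brain_amps = 2, n_mh_items = 5,
                       n_pa_measures = 4, missing_rate = 0,
                       confound_effect = 0, seed = 8)
  co <- generate_cohort(cfg)
  pa <- pt_matrix(standardize_pa(co$pa))
  emp <- stats::cancor(pt_matrix(co$brain), pa)$cor
  expect_equal(emp[1:2], c(0.3, 0.12), tolerance = 0.01)
  expect_equal(population_canonical_correlations(cfg, "pa")[1:2],
               c(0.3, 0.12), tolerance = 1e-10)
  # latent (pre-discretisation) mental-health block obeys the same truth
  mh_lat <- attr(co, "truth")$mh_latent
  emp_mh <- stats::cancor(pt_matrix(co$brain), mh_lat)$cor
  expect_equal(emp_mh[1:2], c(0.3, 0.12), tolerance = 0.01)
})

test_that("independence case shows only sampling noise", {
  for (s in 1:3) {
    cfg <- cohort_config(n_subjects = 6000, canonical_rhos = 0,
                         n_brain_edges = 3, n_brain_amps = 1, n_mh_items = 4,
                         n_pa_measures = 3, missing_rate = 0,
                         confound_effect = 0, seed = s)
    co <- generate_cohort(cfg)
    r1 <- stats::cancor(pt_matrix(co$brain),
                        pt_matrix(standardize_pa(co$pa)))$cor[1]
    expect_lt(r1, 0.08)
  }
})

test_that("empirical covariance converges to the analytic covariance", {
  cfg <- cohort_config(n_subjects = 50000, canonical_rhos = c(0.3, 0.2),
                       n_brain_edges = 3, n_brain_amps = 2, n_mh_items = 4,
                       n_pa_measures = 3, missing_rate = 0,
                       confound_effect = 0, seed = 3)
  co <- generate_cohort(cfg)
  L <- sharedarch:::cohort_loadings(cfg)
  obs <- cbind(pt_matrix(co$brain), attr(co, "truth")$mh_latent,
               pt_matrix(standardize_pa(co$pa)))
  ana <- tcrossprod(rbind(L$brain, L$mh, L$pa))
  expect_lt(max(abs(stats::cov(obs) - ana)), 0.04)
})

test_that("missingness rate and mechanism behave as configured", {
  cfg <- cohort_config(n_subjects = 6000, canonical_rhos = 0.2,
                       missing_rate = 0.35, seed = 2)
  co <- generate_cohort(cfg)
  frac <- colMeans(missing_mask(co$mh_items))
  expect_true(all(abs(frac - 0.35) <= 0.03))

  # MAR: missingness depends on age through a logistic link
  cfgm <- cohort_config(n_subjects = 8000, canonical_rhos = 0.2,
                        missing_rate = 0.3, missing_mechanism = "MAR",
                        seed = 2)
  com <- generate_cohort(cfgm)
  mis <- missing_mask(com$mh_items)[, 1]
  age <- com$confounds$age
  expect_equal(mean(mis), 0.3, tolerance = 0.03)
  expect_gt(mean(age[mis]) - mean(age[!mis]), 0.3)
})

test_that("ordinal items use declared level sets; missing entries are NA", {
  cfg <- small_cohort(5, miss = 0.2)
  co <- generate_cohort(cfg)
  items <- as.data.frame(co$mh_items)
  for (j in seq_along(items)) {
    v <- items[[j]]
    expect_true(all(v[!is.na(v)] %in% seq_len(cfg$item_levels[j])))
  }
  expect_gt(sum(is.na(items)), 0)
})

test_that("same seed reproduces the cohort bit-for-bit", {
  a <- generate_cohort(small_cohort(7))
  b <- generate_cohort(small_cohort(7))
  for (t in c("brain", "mh_items", "pa", "confounds")) {
    expect_identical(as.data.frame(a[[t]]), as.data.frame(b[[t]]))
  }
})

test_that("infeasible canonical targets fail naming the offending index", {
  expect_error(cohort_config(canonical_rhos = c(0.95, 0.1)),
               "canonical_rhos\\[1\\]")
  expect_error(cohort_config(canonical_rhos = c(0.3, 0.4)), "non-increasing")
  expect_error(cohort_config(canonical_rhos = 1.0), "\\[0, 1\\)")
  expect_error(cohort_config(missing_rate = 0.99), "missing_rate")
})

test_that("null GWAS yields mean chi-square of 1", {
  cfg <- sumstats_config(m_snps = 20000, h2_1 = 0, h2_2 = 0, rho_g = 0,
                         seed = 1)
  d <- generate_sumstats(cfg)
  expect_equal(mean(d$ss1$Z^2), 1, tolerance = 0.03)
  expect_equal(mean(d$ss2$Z^2), 1, tolerance = 0.03)
})

test_that("mean chi-square matches the plug-in LDSC expectation", {
  # near-constant LD scores (l_j -> 1): E[chi2] = 1 + N h2 / M = 1.2
  cfg <- sumstats_config(m_snps = 50000, n1 = 1e5, n2 = 1e5,
                         h2_1 = 0.10, h2_2 = 0.10, rho_g = 0,
                         ld_scale = 1e-9, seed = 4)
  d <- generate_sumstats(cfg)
  expect_equal(mean(d$ss1$Z^2), 1.2, tolerance = 0.03)
})

test_that("sumstats generation is seed-reproducible and PSD-guarded", {
  cfg <- sumstats_config(m_snps = 5000, seed = 9)
  expect_identical(generate_sumstats(cfg)$ss1$Z, generate_sumstats(cfg)$ss1$Z)
  expect_error(sumstats_config(h2_1 = 1.5), "h2")
  expect_error(sumstats_config(h2_1 = 0.5, h2_2 = 0.5, rho_g = 0.6), "rg")
})

test_that("text dialects round-trip", {
  d <- generate_sumstats(sumstats_config(m_snps = 500, seed = 2))
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "t1.sumstats")
  write_sumstats(d$ss1, f)
  back <- read_sumstats(f)
  expect_equal(back$Z, d$ss1$Z, tolerance = 1e-12)
  expect_equal(back$SNP, d$ss1$SNP)

  g <- file.path(tmp, "ld.tsv")
  write_ldscores(d$ld, g)
  ldb <- read_ldscores(g)
  expect_equal(ldb$L2, d$ld$L2, tolerance = 1e-12)
  expect_identical(attr(ldb, "M"), 500L)

  co <- generate_cohort(small_cohort(1, miss = 0.2))
  p <- file.path(tmp, "mh.tsv")
  write_pheno_table(co$mh_items, p)
  pb <- read_pheno_table(p)
  expect_equal(as.data.frame(pb), as.data.frame(co$mh_items))
  expect_identical(unname(var_kinds(pb)), rep("ordinal", ncol(pb)))
})
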