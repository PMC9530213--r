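test_that("noiseless chi-square recovers heritability exactly", {
  set.seed(1)
  M <- 5000
  l <- 1 + rgamma(M, 2, scale = 20)
  N <- 1e5; h2 <- 0.17
  ss <- structure(data.frame(SNP = sprintf("rs%05d", 1:M), A1 = "A", A2 = "G",
                             Z = sqrt(1 + N * h2 * l / M), N = N),
                  class = c("sumstats", "data.frame"))
  ld <- structure(data.frame(SNP = ss$SNP, L2 = l), M = M,
                  class = c("ldscore_table", "data.frame"))
  fit <- estimate_h2(ss, ld)
  expect_equal(fit$h2, h2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
})

test_that("null GWAS gives slope near zero and intercept near one", {
  d <- generate_sumstats(sumstats_config(m_snps = 30000, h2_1 = 0, h2_2 = 0,
                                         rho_g = 0, seed = 2))
  fit <- suppressWarnings(estimate_h2(d$ss1, d$ld))
  expect_lt(abs(fit$h2), 3 * fit$h2_se)
  expect_equal(fit$intercept, 1, tolerance = 0.05)
})

test_that("a trait against itself has genetic correlation exactly 1", {
  d <- generate_sumstats(sumstats_config(m_snps = 20000, seed = 3))
  r <- estimate_rg(d$ss1, d$ss1, d$ld)
  expect_equal(r$rg, 1, tolerance = 1e-10)
})

test_that("estimate_rg is symmetric in its arguments", {
  d <- generate_sumstats(sumstats_config(m_snps = 20000, seed = 4))
  a <- estimate_rg(d$ss1, d$ss2, d$ld)
  b <- estimate_rg(d$ss2, d$ss1, d$ld)
  expect_equal(a$rg, b$rg, tolerance = 1e-10)
})

test_that("allele flips negate Z but leave rg unchanged", {
  d <- generate_sumstats(sumstats_config(m_snps = 20000, seed = 5))
  flipped <- d$ss2
  tmp <- flipped$A1; flipped$A1 <- flipped$A2; flipped$A2 <- tmp
  flipped$Z <- -flipped$Z
  a <- estimate_rg(d$ss1, d$ss2, d$ld)
  b <- estimate_rg(d$ss1, flipped, d$ld)
  expect_equal(a$rg, b$rg, tolerance = 1e-12)
  # mismatching allele pairs are dropped
  bad <- d$ss2
  bad$A1[1:5000] <- "T"; bad$A2[1:5000] <- "A"
  keepers <- sum(bad$A1 == d$ss1$A1 | bad$A1 == d$ss1$A2)
  r <- estimate_rg(d$ss1, bad, d$ld)
  expect_lt(r$n_snps, nrow(d$ss1))
})

test_that("merging below 200 SNPs fails; rg undefined for null traits", {
  d <- generate_sumstats(sumstats_config(m_snps = 100, seed = 6))
  expect_error(estimate_h2(d$ss1, d$ld), "200 SNPs")
  # a trait whose chi-square decreases in LD score has negative estimated
  # heritability: rg is then undefined by construction
  set.seed(7)
  M <- 5000
  l <- 1 + rgamma(M, 2, scale = 20)
  neg <- structure(data.frame(SNP = sprintf("rs%05d", 1:M), A1 = "A",
                              A2 = "G", Z = sqrt(pmax(1.5 - 0.4 * l / mean(l), 0.1)),
                              N = 1e5),
                   class = c("sumstats", "data.frame"))
  pos <- generate_sumstats(sumstats_config(m_snps = M, seed = 8))$ss1
  pos$SNP <- neg$SNP; pos$A1 <- neg$A1; pos$A2 <- neg$A2
  ldm <- structure(data.frame(SNP = neg$SNP, L2 = l), M = M,
                   class = c("ldscore_table", "data.frame"))
  expect_true(suppressWarnings(estimate_h2(neg, ldm))$negative)
  expect_error(suppressWarnings(estimate_rg(neg, pos, ldm)),
               "non-positive heritability")
})

test_that("genetic covariance matrix has the documented shape", {
  d <- generate_sumstats(sumstats_config(m_snps = 20000, seed = 8))
  gc <- build_genetic_covariance(list(a = d$ss1, b = d$ss2), d$ld)
  expect_identical(dim(gc$S), c(2L, 2L))
  expect_true(isSymmetric(gc$S))
  expect_equal(diag(gc$R), c(a = 1, b = 1))
  # 3 unique elements of S (2 heritabilities + 1 covariance), V is 3x3
  expect_identical(dim(gc$V), c(3L, 3L))
  expect_identical(rownames(gc$V), c("h2:a", "h2:b", "cov:a:b"))
  expect_identical(nrow(gc$pairs), 1L)
})

test_that("one-factor truth shows up as proportional off-diagonals", {
  lam <- c(a = 0.8, b = 0.7, c = 0.6, d = 0.5)
  s <- generate_sumstats_set(lam, h2 = 0.2, n = 2e5, m_snps = 30000, seed = 9)
  gc <- build_genetic_covariance(s$ss, s$ld)
  truth <- tcrossprod(lam); diag(truth) <- 1
  expect_lt(max(abs(gc$R - truth)), 0.08)
})

test_that("all-null phenotypes rarely pass FDR", {
  s <- generate_sumstats_set(c(a = 0, b = 0, c = 0, d = 0, e = 0), h2 = 0.1,
                             n = 1e5, m_snps = 20000, seed = 10)
  gc <- build_genetic_covariance(s$ss, s$ld)
  flagged <- fdr_correct_pairs(gc$pairs, q = 0.05)
  expect_lte(sum(flagged$significant), 1)
})

test_that("BH correction over a declared family", {
  res <- data.frame(p = c(0.01, 0.02, 0.03, 0.04))
  out <- fdr_correct_pairs(res, q = 0.05)
  expect_equal(out$p_fdr, bh_oracle_adjust(res$p))
  expect_true(all(out$significant))  # largest k with p_(k) <= k q/m is 4
  expect_true(all(out$p_fdr >= out$p))
  one <- fdr_correct_pairs(data.frame(p = 0.03))
  expect_equal(one$p_fdr, 0.03)
})
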