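#' @keywords internal
# Merge two sumstats sets with an LD-score table on SNP id, aligning alleles:
# Z of the second set is sign-flipped where A1/A2 are swapped; SNPs whose
# allele pairs do not match are dropped.
merge_sumstats <- function(ss1, ss2, ld) {
  m <- merge(merge(ld, ss1, by = "SNP"), ss2, by = "SNP",
             suffixes = c("1", "2"))
  m <- m[order(match(m$SNP, ld$SNP)), ]
  same <- m$A11 == m$A12 & m$A21 == m$A22
  swap <- m$A11 == m$A22 & m$A21 == m$A12
  m$Z2[swap] <- -m$Z2[swap]
  m <- m[same | swap, , drop = FALSE]
  rownames(m) <- NULL
  m
}

# Weighted 2-parameter regression (intercept + slope) with contiguous-block
# jackknife.  Weights are held fixed across delete-block refits.  Returns
# the fit plus the B x 2 matrix of delete-one-block estimates.
wreg_blocks <- function(y, x, w, n_blocks) {
  n <- length(y)
  B <- min(n_blocks, n)
  blk <- ceiling(seq_along(y) / (n / B))
  blk[blk > B] <- B
  agg <- function(v) {
    s <- rowsum(v, blk)
    list(block = s, total = sum(s))
  }
  a <- agg(w); bx <- agg(w * x); by <- agg(w * y)
  cxx <- agg(w * x * x); cxy <- agg(w * x * y)
  est <- function(A, Bx, By, Cxx, Cxy) {
    den <- A * Cxx - Bx^2
    slope <- (A * Cxy - Bx * By) / den
    icpt <- (By - slope * Bx) / A
    cbind(icpt, slope)
  }
  fit <- est(a$total, bx$total, by$total, cxx$total, cxy$total)
  jk <- est(a$total - a$block, bx$total - bx$block, by$total - by$block,
            cxx$total - cxx$block, cxy$total - cxy$block)
  list(coef = drop(fit), jk = jk, n_blocks = B, blocks = blk)
}

jackknife_se <- function(theta_b) {
  B <- nrow(as.matrix(theta_b))
  th <- as.matrix(theta_b)
  mu <- colMeans(th)
  sqrt((B - 1) / B * colSums(sweep(th, 2, mu)^2))
}

jackknife_cov <- function(theta_b) {
  th <- as.matrix(theta_b)
  B <- nrow(th)
  d <- sweep(th, 2, colMeans(th))
  (B - 1) / B * crossprod(d)
}

# two-pass heteroskedasticity weights for the chi^2 regression
h2_weights <- function(l, x, pass1_icpt, pass1_slope) {
  ev <- pmax(pass1_icpt + pmax(pass1_slope, 0) * x, 0.1)
  1 / (pmax(l, 1) * ev^2)
}

#' SNP heritability by LD score regression
#'
#' Weighted regression of \eqn{\chi^2_j = Z_j^2} on \eqn{N_j \ell_j / M}
#' with a free intercept; the slope is the SNP heritability and the
#' intercept captures confounding inflation.  Weights follow the canonical
#' two-step scheme: a first pass with `1/l` weights, then inverse squared
#' expected outcome.  Standard errors come from a delete-one block jackknife
#' over contiguous SNP blocks.
#'
#' @param ss a `sumstats` data.frame.
#' @param ld an `ldscore_table`.
#' @param n_blocks jackknife blocks (default 200).
#' @return List with `h2`, `h2_se`, `intercept`, `intercept_se`, `n_snps`,
#'   `negative` flag (negative point estimates are returned, flagged, never
#'   clamped), and the delete-block estimates `jk`.
#' @export
estimate_h2 <- function(ss, ld, n_blocks = 200) {
  m <- merge(ld, ss, by = "SNP")
  m <- m[order(match(m$SNP, ld$SNP)), ]
  if (nrow(m) < 200) stop("fewer than 200 SNPs after merging")
  M <- ld_m(ld)
  chi2 <- m$Z^2
  x <- m$N * m$L2 / M
  f1 <- wreg_blocks(chi2, x, 1 / pmax(m$L2, 1), n_blocks)
  w <- h2_weights(m$L2, x, f1$coef[1], f1$coef[2])
  f2 <- wreg_blocks(chi2, x, w, n_blocks)
  se <- jackknife_se(f2$jk)
  h2 <- unname(f2$coef[2])
  if (h2 < 0) warning("negative heritability estimate", call. = FALSE)
  list(h2 = h2, h2_se = unname(se[2]),
       intercept = unname(f2$coef[1]), intercept_se = unname(se[1]),
       n_snps = nrow(m), negative = h2 < 0, jk = f2$jk)
}

#' Cross-trait genetic correlation by LD score regression
#'
#' Weighted regression of \eqn{Z_{1j} Z_{2j}} on
#' \eqn{\sqrt{N_1 N_2}\,\ell_j / M}: the slope is the genetic covariance
#' \eqn{\rho_g} and the free intercept absorbs sample overlap.  The genetic
#' correlation is \eqn{r_g = \rho_g / \sqrt{h^2_1 h^2_2}} with the
#' heritabilities estimated on the merged SNP set; its SE comes from a
#' joint delete-one-block jackknife of the full ratio.
#'
#' @param ss1,ss2 `sumstats` data.frames (alleles are aligned; swapped
#'   A1/A2 flips the Z sign).
#' @param ld an `ldscore_table`.
#' @param n_blocks jackknife blocks.
#' @return List with `rg`, `rg_se`, `p` (two-sided normal), `rho_g`,
#'   `cross_intercept`, the per-trait `h2` estimates, `n_snps`, and the
#'   delete-block `jk_rg`.
#' @export
estimate_rg <- function(ss1, ss2, ld, n_blocks = 200) {
  m <- merge_sumstats(ss1, ss2, ld)
  if (nrow(m) < 200) stop("fewer than 200 SNPs after merging")
  M <- ld_m(ld)
  l <- m$L2
  x1 <- m$N1 * l / M
  x2 <- m$N2 * l / M
  xc <- sqrt(m$N1 * m$N2) * l / M

  p1a <- wreg_blocks(m$Z1^2, x1, 1 / pmax(l, 1), n_blocks)
  p1b <- wreg_blocks(m$Z2^2, x2, 1 / pmax(l, 1), n_blocks)
  p1c <- wreg_blocks(m$Z1 * m$Z2, xc, 1 / pmax(l, 1), n_blocks)

  w1 <- h2_weights(l, x1, p1a$coef[1], p1a$coef[2])
  w2 <- h2_weights(l, x2, p1b$coef[1], p1b$coef[2])
  v1 <- pmax(p1a$coef[1] + pmax(p1a$coef[2], 0) * x1, 0.1)
  v2 <- pmax(p1b$coef[1] + pmax(p1b$coef[2], 0) * x2, 0.1)
  cc <- p1c$coef[1] + p1c$coef[2] * xc
  wc <- 1 / (pmax(l, 1) * (v1 * v2 + cc^2))

  fa <- wreg_blocks(m$Z1^2, x1, w1, n_blocks)
  fb <- wreg_blocks(m$Z2^2, x2, w2, n_blocks)
  fc <- wreg_blocks(m$Z1 * m$Z2, xc, wc, n_blocks)

  h2_1 <- fa$coef[2]; h2_2 <- fb$coef[2]; rho_g <- fc$coef[2]
  if (h2_1 <= 0 || h2_2 <= 0) {
    stop("non-positive heritability: genetic correlation undefined")
  }
  rg <- unname(rho_g / sqrt(h2_1 * h2_2))
  jk_rg <- fc$jk[, 2] / sqrt(pmax(fa$jk[, 2], 1e-12) * pmax(fb$jk[, 2], 1e-12))
  se <- jackknife_se(jk_rg)
  list(rg = rg, rg_se = unname(se),
       p = 2 * stats::pnorm(-abs(rg / se)),
       rho_g = unname(rho_g), cross_intercept = unname(fc$coef[1]),
       h2_1 = unname(h2_1), h2_2 = unname(h2_2),
       intercept_1 = unname(fa$coef[1]), intercept_2 = unname(fb$coef[1]),
       n_snps = nrow(m), jk_rg = jk_rg,
       jk = cbind(icpt_1 = fa$jk[, 1], h2_1 = fa$jk[, 2],
                  icpt_2 = fb$jk[, 1], h2_2 = fb$jk[, 2],
                  cross_icpt = fc$jk[, 1], rho_g = fc$jk[, 2], rg = jk_rg))
}

#' Multi-phenotype genetic covariance matrix
#'
#' Runs [estimate_h2()] and [estimate_rg()] over all phenotype pairs on the
#' common SNP set and assembles the genetic covariance matrix `S`
#' (heritabilities on the diagonal, genetic covariances off it), the genetic
#' correlation matrix `R`, and the joint block-jackknife sampling covariance
#' `V` of the unique elements of `R` (off-diagonals, in column-major lower
#' triangle order), which captures their sampling covariances for
#' downstream structural modelling.
#'
#' @param ss_list named list of `sumstats` (>= 2).
#' @param ld an `ldscore_table`.
#' @param n_blocks jackknife blocks.
#' @return An object of class `genetic_covariance`: list with `S`, `R`, `V`,
#'   `h2` (named vector), `h2_se`, `pairs` (data.frame with per-pair rg, SE,
#'   p), `labels`.
#' @export
build_genetic_covariance <- function(ss_list, ld, n_blocks = 200) {
  k <- length(ss_list)
  if (k < 2) stop("need at least 2 phenotypes")
  labels <- names(ss_list)
  if (is.null(labels)) labels <- paste0("trait", seq_len(k))

  S <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  R <- S
  h2 <- stats::setNames(numeric(k), labels)
  h2_se <- h2
  pairs <- NULL
  jk_rg_list <- list()    # delete-block rg per pair (for V of R)
  jk_s_list <- list()     # delete-block h2 / rho_g (for V of S)
  for (i in seq_len(k)) {
    hi <- estimate_h2(ss_list[[i]], ld, n_blocks)
    S[i, i] <- hi$h2; R[i, i] <- 1
    h2[i] <- hi$h2; h2_se[i] <- hi$h2_se
    jk_s_list[[paste0("h2:", labels[i])]] <- hi$jk[, 2]
  }
  for (j in seq_len(k - 1)) {
    for (i in (j + 1):k) {
      res <- tryCatch(estimate_rg(ss_list[[j]], ss_list[[i]], ld, n_blocks),
                      error = function(e) e)
      nm <- paste(labels[j], labels[i], sep = ":")
      if (inherits(res, "error")) {
        pairs <- rbind(pairs, data.frame(trait1 = labels[j], trait2 = labels[i],
                                         rg = NA, rg_se = NA, p = NA))
        next
      }
      S[i, j] <- S[j, i] <- res$rho_g
      R[i, j] <- R[j, i] <- res$rg
      pairs <- rbind(pairs, data.frame(trait1 = labels[j], trait2 = labels[i],
                                       rg = res$rg, rg_se = res$rg_se,
                                       p = res$p))
      jk_rg_list[[nm]] <- res$jk_rg
      jk_s_list[[paste0("cov:", nm)]] <- res$jk[, "rho_g"]
    }
  }
  # joint sampling covariances require a shared block partition, which holds
  # when all traits cover the same SNP panel (as synthetic sets do)
  nb <- vapply(jk_s_list, length, integer(1))
  V_S <- if (length(unique(nb)) == 1)
    jackknife_cov(do.call(cbind, jk_s_list)) else NULL
  V_rg <- if (length(jk_rg_list) &&
              length(unique(vapply(jk_rg_list, length, integer(1)))) == 1)
    jackknife_cov(do.call(cbind, jk_rg_list)) else NULL
  structure(list(S = S, R = R, V = V_S, V_rg = V_rg, h2 = h2, h2_se = h2_se,
                 pairs = pairs, labels = labels),
            class = "genetic_covariance")
}

#' @export
print.genetic_covariance <- function(x, ...) {
  cat(sprintf("<genetic_covariance> %d phenotypes\n", length(x$labels)))
  cat("  h2:", sprintf("%s=%.3f", x$labels, x$h2), "\n")
  invisible(x)
}

#' Benjamini–Hochberg correction over a declared test family
#'
#' @param results data.frame with a `p` column (one row per test in the
#'   family).
#' @param q FDR level.
#' @return `results` with `p_fdr` and `significant` columns appended.
#' @export
fdr_correct_pairs <- function(results, q = 0.05) {
  results$p_fdr <- stats::p.adjust(results$p, method = "BH")
  results$significant <- !is.na(results$p_fdr) & results$p_fdr <= q
  results
}
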