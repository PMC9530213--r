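#' Latent causal variable analysis: genetic causality proportion
#'
#' Posits a latent mediator L of the genetic correlation between two traits,
#' with per-SNP standardized effects \eqn{\alpha_i = q_i \pi + \delta_i}.
#' Under heavy-tailed \eqn{\pi} (excess kurtosis \eqn{\kappa}), the
#' noise-corrected mixed moments
#' \eqn{m_{31} = E[\alpha_1^3\alpha_2] - 3\rho = \kappa q_1^3 q_2} and
#' \eqn{m_{13} = E[\alpha_1\alpha_2^3] - 3\rho = \kappa q_1 q_2^3}
#' identify the loading ratio \eqn{q_2^2/q_1^2 = m_{13}/m_{31}}, and the
#' genetic causality proportion is
#' \deqn{GCP = \log(q_2^2/q_1^2) / \log(\rho^2) \in [-1, 1],}
#' positive when trait 1 is partially causal for trait 2 (+1 = full
#' causality), negative in the reverse direction, 0 under symmetric
#' pleiotropy.  Effects are normalized by the LDSC heritabilities and the
#' per-SNP noise contribution (including the cross-trait intercept) is
#' subtracted from the moments; SNPs are weighted by `1/l` to de-emphasize
#' high-LD regions.  SE and p come from a delete-one block jackknife (100
#' blocks: fourth moments are noisier than LDSC second moments).
#'
#' GCP is unidentified when genetic effects are exactly normally distributed
#' (\eqn{\kappa = 0}); the estimator assumes a heavy-tailed architecture.
#'
#' @param ss1,ss2 `sumstats` data.frames.
#' @param ld an `ldscore_table`.
#' @param n_blocks jackknife blocks (default 100).
#' @param min_snps minimum merged SNP count (fourth moments need support).
#' @return An object of class `lcv_result`: `gcp`, `se`, `z`, `p`, `rg`
#'   (the LDSC genetic correlation used), `underpowered` flag (set when
#'   `|rg|` is below twice its SE; `p` is then 1).
#' @export
estimate_gcp <- function(ss1, ss2, ld, n_blocks = 100, min_snps = 2000) {
  m <- merge_sumstats(ss1, ss2, ld)
  if (nrow(m) < min_snps) stop("fewer than ", min_snps, " SNPs after merging")
  M <- ld_m(ld)
  base <- estimate_rg(ss1, ss2, ld, n_blocks = n_blocks)
  if (base$h2_1 <= 0 || base$h2_2 <= 0) stop("non-positive heritability")
  rho <- max(min(base$rg, 1), -1)

  if (abs(base$rg) < 2 * base$rg_se) {
    return(structure(list(gcp = 0, se = NA_real_, z = 0, p = 1,
                          rg = base$rg, underpowered = TRUE),
                     class = "lcv_result"))
  }

  l <- m$L2
  w <- 1 / pmax(l, 1)
  B <- min(n_blocks, nrow(m))
  blk <- ceiling(seq_along(l) / (nrow(m) / B))
  blk[blk > B] <- B

  # Raw blockwise sums, independent of any estimated normalization.  With
  # x_i = Z_i / (a_i sqrt(l)), a_i = sqrt(N_i h2_i / M), the noise-corrected
  # mixed moments expand into these ingredients scaled by powers of a_i and
  # the LDSC intercepts, so every delete-block statistic can be recomputed
  # with that block's own heritabilities/intercepts — the jackknife then
  # carries the normalization noise, which otherwise deflates the SE.
  raw <- cbind(w = w,
               A = w * m$Z1^3 * m$Z2 / l^2,     # for x1^3 x2
               Bq = w * m$Z1 * m$Z2^3 / l^2,    # for x1 x2^3
               C = w * m$Z1 * m$Z2 / l^2,       # for x1 x2 * v_i
               E1 = w * m$Z1^2 / l^2,           # for (x1^2 - v1) c12
               E2 = w * m$Z2^2 / l^2,
               FF = w / l^2)
  bs <- rowsum(raw, blk)
  tot <- colSums(bs)

  moments <- function(s, h2_1, h2_2, i1, i2, cc) {
    a1sq <- m$N1[1] * h2_1 / M
    a2sq <- m$N2[1] * h2_2 / M
    n31 <- (s["A"] - 3 * i1 * s["C"] - 3 * cc * (s["E1"] - i1 * s["FF"])) /
      (a1sq^1.5 * sqrt(a2sq))
    n13 <- (s["Bq"] - 3 * i2 * s["C"] - 3 * cc * (s["E2"] - i2 * s["FF"])) /
      (sqrt(a1sq) * a2sq^1.5)
    c(m31 = unname(n31 / s["w"]), m13 = unname(n13 / s["w"]))
  }
  gcp_of <- function(mm, rho_b) {
    # q1^2 / q2^2 = (m31 - 3 rho) / (m13 - 3 rho); rho terms already netted
    # out against the kappa products below
    m31 <- mm["m31"] - 3 * rho_b
    m13 <- mm["m13"] - 3 * rho_b
    ratio <- abs(m13) / pmax(abs(m31), 1e-12)
    unname(pmin(pmax(log(ratio) / log(pmax(rho_b^2, 1e-12)), -1), 1))
  }

  jk <- base$jk  # delete-block icpt/h2/cross-icpt/rho_g/rg, same partition
  if (nrow(jk) != B) stop("internal: jackknife block mismatch")
  mm <- moments(tot, base$h2_1, base$h2_2, base$intercept_1,
                base$intercept_2, base$cross_intercept)
  gcp <- gcp_of(mm, rho)
  rho_jk <- pmin(pmax(base$jk_rg, -1), 1)
  gcp_b <- D_b <- numeric(B)
  for (b in seq_len(B)) {
    mm_b <- moments(tot - bs[b, ], jk[b, "h2_1"], jk[b, "h2_2"],
                    jk[b, "icpt_1"], jk[b, "icpt_2"], jk[b, "cross_icpt"])
    gcp_b[b] <- gcp_of(mm_b, rho_jk[b])
    D_b[b] <- mm_b["m31"] - mm_b["m13"]
  }
  se <- jackknife_se(gcp_b)
  # the causality test uses the difference of mixed moments, which is nearly
  # linear in the block sums, so its block jackknife is well calibrated (the
  # GCP log-ratio itself is too nonlinear for delete-one variance estimation)
  D <- unname(mm["m31"] - mm["m13"])
  z <- D / max(jackknife_se(D_b), 1e-300)
  structure(list(gcp = unname(gcp), se = unname(se), z = unname(z),
                 p = 2 * stats::pnorm(-abs(z)), rg = base$rg,
                 underpowered = FALSE),
            class = "lcv_result")
}

#' @export
print.lcv_result <- function(x, ...) {
  cat(sprintf("<lcv_result> GCP = %.3f (SE %.3f), p = %.3g, rg = %.3f%s\n",
              x$gcp, x$se, x$p, x$rg,
              if (x$underpowered) " [underpowered]" else ""))
  invisible(x)
}
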