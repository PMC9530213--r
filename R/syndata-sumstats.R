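#' Configuration for synthetic GWAS summary statistics
#'
#' Describes a pair of traits whose per-SNP Z-scores obey the LD score
#' regression moment model:
#' \deqn{Var(Z_{ij}) = 1 + N_i h^2_i \ell_j / M, \quad
#'       Cov(Z_{1j}, Z_{2j}) = \sqrt{N_1 N_2}\,\rho_g \ell_j / M + c}
#' where \eqn{\ell_j} is SNP j's LD score, \eqn{M} the SNP count and
#' \eqn{c} a sample-overlap intercept.  When `lcv_mode != "none"` the
#' per-SNP standardized genetic effects are drawn through a latent-variable
#' architecture \eqn{\alpha_i = q_i \pi + \delta_i} with \eqn{\pi}
#' heavy-tailed (scale mixture of normals), so that mixed third/fourth
#' moments identify the genetic causality proportion:
#' `"causal_1to2"` sets \eqn{q_1 = 1, q_2 = r_g} (GCP = +1),
#' `"causal_2to1"` the reverse (GCP = -1), and `"pleiotropy"` sets
#' \eqn{q_1 = q_2 = \sqrt{|r_g|}} (GCP = 0).
#'
#' @param m_snps number of SNPs M.
#' @param n1,n2 GWAS sample sizes.
#' @param h2_1,h2_2 SNP heritabilities in `[0, 1]`.
#' @param rho_g genetic covariance; the implied genetic correlation
#'   `rg = rho_g / sqrt(h2_1 * h2_2)` must satisfy `|rg| <= 1`.
#' @param sample_overlap_intercept cross-trait LDSC intercept contributed by
#'   overlapping samples, in `[-1, 1]`.
#' @param ld_shape,ld_scale Gamma parameters for LD scores, drawn as
#'   `1 + Gamma(shape, scale)` (right-skewed, always >= 1).
#' @param lcv_mode one of `"none"`, `"pleiotropy"`, `"causal_1to2"`,
#'   `"causal_2to1"`.
#' @param q1,q2 optional explicit latent loadings overriding the mode preset;
#'   they imply `rg = q1 * q2`.
#' @param tail_prob spike probability of the heavy-tailed latent effect
#'   mixture (excess kurtosis `3 * (1/tail_prob - 1)`).
#' @param seed integer seed.
#' @return An object of class `sumstats_config`.
#' @export
sumstats_config <- function(m_snps = 50000, n1 = 100000, n2 = 100000,
                            h2_1 = 0.10, h2_2 = 0.21,
                            rho_g = 0.12 * sqrt(h2_1 * h2_2),
                            sample_overlap_intercept = 0,
                            ld_shape = 2, ld_scale = 20,
                            lcv_mode = c("none", "pleiotropy",
                                         "causal_1to2", "causal_2to1"),
                            q1 = NULL, q2 = NULL,
                            tail_prob = 0.1, seed = 1L) {
  lcv_mode <- match.arg(lcv_mode)
  if (m_snps <= 0) stop("m_snps must be positive")
  if (h2_1 < 0 || h2_1 > 1 || h2_2 < 0 || h2_2 > 1) stop("h2 must lie in [0, 1]")
  rg <- if (h2_1 > 0 && h2_2 > 0) rho_g / sqrt(h2_1 * h2_2) else 0
  if (!is.null(q1) && !is.null(q2)) {
    if (abs(q1) > 1 || abs(q2) > 1) stop("|q| must be <= 1")
    rg <- q1 * q2
    rho_g <- rg * sqrt(h2_1 * h2_2)
  }
  if (abs(rg) > 1 + 1e-12) stop("implied |rg| exceeds 1")
  if (abs(sample_overlap_intercept) > 1) {
    stop("sample_overlap_intercept must lie in [-1, 1]")
  }
  structure(list(
    m_snps = as.integer(m_snps), n1 = n1, n2 = n2, h2_1 = h2_1, h2_2 = h2_2,
    rho_g = rho_g, rg = rg,
    sample_overlap_intercept = sample_overlap_intercept,
    ld_shape = ld_shape, ld_scale = ld_scale,
    lcv_mode = lcv_mode, q1 = q1, q2 = q2, tail_prob = tail_prob,
    seed = as.integer(seed)
  ), class = "sumstats_config")
}

#' Generate a pair of GWAS summary-statistics sets plus LD scores
#'
#' @param config a [sumstats_config()].
#' @param labels length-2 character vector of phenotype labels.
#' @return A list with elements `ss1`, `ss2` (class `sumstats`: data.frames
#'   with columns `SNP`, `A1`, `A2`, `Z`, `N`), `ld` (class `ldscore_table`:
#'   columns `SNP`, `L2`, attribute `M`), and `truth` (the generative
#'   parameters, including the latent loadings `q1`, `q2` and the implied
#'   population GCP).
#' @export
generate_sumstats <- function(config, labels = c("trait1", "trait2")) {
  stopifnot(inherits(config, "sumstats_config"))
  set.seed(config$seed)
  M <- config$m_snps
  l <- 1 + stats::rgamma(M, shape = config$ld_shape, scale = config$ld_scale)

  # per-SNP genetic effect variances under the LDSC moment model
  v1 <- config$h2_1 * l / M
  v2 <- config$h2_2 * l / M
  rg <- config$rg
  icpt <- config$sample_overlap_intercept

  # per-SNP Z covariance must be PSD: with |rg|<=1 and |icpt|<=1 it always
  # is, but guard against pathological inputs explicitly
  det_min <- (1 + config$n1 * v1) * (1 + config$n2 * v2) -
    (sqrt(config$n1 * config$n2) * rg * sqrt(v1 * v2) + icpt)^2
  if (any(det_min < -1e-8)) {
    stop(sprintf("per-SNP Z covariance not positive semi-definite at SNP %d",
                 which(det_min < -1e-8)[1]))
  }

  mode <- config$lcv_mode
  if (mode == "none") {
    x1 <- stats::rnorm(M)
    x2 <- rg * x1 + sqrt(max(0, 1 - rg^2)) * stats::rnorm(M)
  } else {
    qq <- switch(mode,
      pleiotropy = c(sqrt(abs(rg)), sign(rg + (rg == 0)) * sqrt(abs(rg))),
      causal_1to2 = c(1, rg),
      causal_2to1 = c(rg, 1))
    if (!is.null(config$q1) && !is.null(config$q2)) {
      qq <- c(config$q1, config$q2)
    }
    p <- config$tail_prob
    spike <- stats::runif(M) < p
    pi_lat <- stats::rnorm(M) * ifelse(spike, 1 / sqrt(p), 0)
    x1 <- qq[1] * pi_lat + sqrt(max(0, 1 - qq[1]^2)) * stats::rnorm(M)
    x2 <- qq[2] * pi_lat + sqrt(max(0, 1 - qq[2]^2)) * stats::rnorm(M)
  }
  b1 <- sqrt(v1) * x1
  b2 <- sqrt(v2) * x2

  e1 <- stats::rnorm(M)
  e2 <- icpt * e1 + sqrt(max(0, 1 - icpt^2)) * stats::rnorm(M)
  z1 <- sqrt(config$n1) * b1 + e1
  z2 <- sqrt(config$n2) * b2 + e2

  snp <- sprintf("rs%07d", seq_len(M))
  pairs <- rbind(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"))
  pick <- sample.int(4, M, replace = TRUE)
  a1 <- pairs[pick, 1]; a2 <- pairs[pick, 2]

  mk_ss <- function(z, n, label) {
    structure(data.frame(SNP = snp, A1 = a1, A2 = a2, Z = z, N = n,
                         stringsAsFactors = FALSE),
              phenotype = label, class = c("sumstats", "data.frame"))
  }
  ld <- structure(data.frame(SNP = snp, L2 = l, stringsAsFactors = FALSE),
                  M = M, class = c("ldscore_table", "data.frame"))
  truth <- list(config = config,
                q = if (mode == "none") NULL else qq,
                gcp = switch(mode, none = NA_real_, pleiotropy = 0,
                             causal_1to2 = 1, causal_2to1 = -1))
  list(ss1 = mk_ss(z1, config$n1, labels[1]),
       ss2 = mk_ss(z2, config$n2, labels[2]),
       ld = ld, truth = truth)
}

#' Read/write the summary-statistics and LD-score text dialects
#'
#' Summary statistics use the de-facto whitespace-delimited layout with
#' columns `SNP A1 A2 Z N`; LD scores are tab-separated with columns
#' `SNP L2` and carry the total SNP count `M` in a `# M=` header comment
#' (defaults to the row count when absent).
#'
#' @param ss a `sumstats` data.frame.
#' @param path file path.
#' @return Readers return the parsed object; writers return `path` invisibly.
#' @export
write_sumstats <- function(ss, path) {
  utils::write.table(ss, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @param label phenotype label to attach on read.
#' @export
read_sumstats <- function(path, label = basename(path)) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("SNP", "A1", "A2", "Z", "N")
  if (!all(need %in% names(df))) {
    stop("sumstats file must have columns ", paste(need, collapse = " "))
  }
  if (anyDuplicated(df$SNP)) stop("duplicate SNP ids in ", path)
  structure(df[need], phenotype = label, class = c("sumstats", "data.frame"))
}

#' @rdname write_sumstats
#' @param ld an `ldscore_table`.
#' @export
write_ldscores <- function(ld, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# M=%d", ld_m(ld)), con)
  utils::write.table(ld, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_ldscores <- function(path) {
  first <- readLines(path, n = 1)
  M <- if (grepl("^# M=", first)) as.integer(sub("^# M=", "", first)) else NA
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (is.na(M)) M <- nrow(df)
  structure(df, M = M, class = c("ldscore_table", "data.frame"))
}

ld_m <- function(ld) {
  M <- attr(ld, "M")
  if (is.null(M)) nrow(ld) else M
}

#' Generate a set of summary-statistics files from a one-factor truth
#'
#' Draws per-SNP standardized genetic effects for `k` traits as
#' \eqn{x_i = \lambda_i f + \sqrt{1 - \lambda_i^2}\, u_i} with a shared
#' factor `f`, so the population genetic correlation matrix is
#' \eqn{\Lambda\Lambda'} off the diagonal.  An optional external block of
#' loadings extends the factor to extra traits.  Useful as ground truth for
#' common-factor structural models and the multi-trait pipeline.
#'
#' @param loadings numeric vector of factor loadings in `[-1, 1]`, one per
#'   trait (named to label the traits).
#' @param h2 SNP heritabilities (recycled).
#' @param n GWAS sample sizes (recycled).
#' @param m_snps SNP count.
#' @param ld_shape,ld_scale LD-score Gamma parameters (scores are
#'   `1 + Gamma`).
#' @param seed integer seed.
#' @return List with `ss` (named list of `sumstats`), `ld`, and `truth`
#'   (loadings and the implied rg matrix).
#' @export
generate_sumstats_set <- function(loadings, h2 = 0.1, n = 100000,
                                  m_snps = 50000, ld_shape = 2,
                                  ld_scale = 20, seed = 1L) {
  k <- length(loadings)
  if (any(abs(loadings) > 1)) stop("|loadings| must be <= 1")
  labels <- names(loadings)
  if (is.null(labels)) labels <- paste0("trait", seq_len(k))
  h2 <- rep_len(h2, k)
  n <- rep_len(n, k)
  set.seed(seed)
  M <- as.integer(m_snps)
  l <- 1 + stats::rgamma(M, shape = ld_shape, scale = ld_scale)
  f <- stats::rnorm(M)
  snp <- sprintf("rs%07d", seq_len(M))
  pairs <- rbind(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"))
  pick <- sample.int(4, M, replace = TRUE)
  ss <- vector("list", k)
  for (i in seq_len(k)) {
    x <- loadings[i] * f + sqrt(1 - loadings[i]^2) * stats::rnorm(M)
    z <- sqrt(n[i] * h2[i] * l / M) * x + stats::rnorm(M)
    ss[[i]] <- structure(
      data.frame(SNP = snp, A1 = pairs[pick, 1], A2 = pairs[pick, 2],
                 Z = z, N = n[i], stringsAsFactors = FALSE),
      phenotype = labels[i], class = c("sumstats", "data.frame"))
  }
  names(ss) <- labels
  ld <- structure(data.frame(SNP = snp, L2 = l, stringsAsFactors = FALSE),
                  M = M, class = c("ldscore_table", "data.frame"))
  rg <- tcrossprod(loadings)
  diag(rg) <- 1
  dimnames(rg) <- list(labels, labels)
  list(ss = ss, ld = ld,
       truth = list(loadings = stats::setNames(loadings, labels), rg = rg,
                    h2 = stats::setNames(h2, labels)))
}

#' Generate two correlated one-factor trait sets on a shared SNP panel
#'
#' Two constructs (e.g. mental health and physical activity) whose traits
#' load on their own common factors `F1`, `F2` with `cor(F1, F2) =
#' factor_cor`, so the population genetic correlation between trait `i` of
#' set 1 and trait `j` of set 2 is `loadings1[i] * loadings2[j] *
#' factor_cor`, and the factor-to-external-trait correlation targeted by a
#' joint structural model is `factor_cor * loadings2[j]`.
#'
#' @param loadings1,loadings2 named loading vectors for the two sets.
#' @param factor_cor correlation between the two factors, in `[-1, 1]`.
#' @param h2_1,h2_2 heritabilities per set (recycled).
#' @param n_1,n_2 GWAS sample sizes per set (recycled).
#' @param m_snps,ld_shape,ld_scale,seed as in [generate_sumstats_set()].
#' @return List with `ss1`, `ss2` (named lists of `sumstats`), shared `ld`,
#'   and `truth`.
#' @export
generate_sumstats_two_sets <- function(loadings1, loadings2, factor_cor,
                                       h2_1 = 0.1, h2_2 = 0.15,
                                       n_1 = 200000, n_2 = 100000,
                                       m_snps = 50000, ld_shape = 2,
                                       ld_scale = 20, seed = 1L) {
  if (abs(factor_cor) > 1) stop("|factor_cor| must be <= 1")
  set.seed(seed)
  M <- as.integer(m_snps)
  l <- 1 + stats::rgamma(M, shape = ld_shape, scale = ld_scale)
  f1 <- stats::rnorm(M)
  f2 <- factor_cor * f1 + sqrt(1 - factor_cor^2) * stats::rnorm(M)
  snp <- sprintf("rs%07d", seq_len(M))
  pairs <- rbind(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"))
  pick <- sample.int(4, M, replace = TRUE)
  draw_set <- function(loadings, h2, n, f) {
    k <- length(loadings)
    labels <- names(loadings)
    if (is.null(labels)) labels <- paste0("trait", seq_len(k))
    h2 <- rep_len(h2, k); n <- rep_len(n, k)
    out <- vector("list", k)
    for (i in seq_len(k)) {
      x <- loadings[i] * f + sqrt(1 - loadings[i]^2) * stats::rnorm(M)
      z <- sqrt(n[i] * h2[i] * l / M) * x + stats::rnorm(M)
      out[[i]] <- structure(
        data.frame(SNP = snp, A1 = pairs[pick, 1], A2 = pairs[pick, 2],
                   Z = z, N = n[i], stringsAsFactors = FALSE),
        phenotype = labels[i], class = c("sumstats", "data.frame"))
    }
    stats::setNames(out, labels)
  }
  ss1 <- draw_set(loadings1, h2_1, n_1, f1)
  ss2 <- draw_set(loadings2, h2_2, n_2, f2)
  ld <- structure(data.frame(SNP = snp, L2 = l, stringsAsFactors = FALSE),
                  M = M, class = c("ldscore_table", "data.frame"))
  list(ss1 = ss1, ss2 = ss2, ld = ld,
       truth = list(loadings1 = loadings1, loadings2 = loadings2,
                    factor_cor = factor_cor))
}
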