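#' Per-subject standardization of physical-activity measures
#'
#' Each activity measure's per-window mean is divided by that subject's
#' day-to-day standard deviation of the measure, removing between-subject
#' scale differences.  The table is expected to hold, for each measure `m`,
#' window columns `m_overall`, `m_weekday`, `m_weekend` and a subject-level
#' SD column `m_sd` (the layout emitted by [generate_cohort()]).  Subjects
#' with zero SD on a measure get missing standardized values; the count is
#' recorded in the `"standardize_log"` attribute.
#'
#' @param pa a `pheno_table` of activity means and `_sd` columns.
#' @return A `pheno_table` with the standardized window means only.
#' @export
standardize_pa <- function(pa) {
  df <- as.data.frame(pa)
  sd_cols <- grep("_sd$", names(df), value = TRUE)
  if (!length(sd_cols)) stop("no `_sd` columns found")
  measures <- sub("_sd$", "", sd_cols)
  out <- df[setdiff(names(df), sd_cols)]
  n_zero <- 0L
  for (m in measures) {
    wins <- grep(paste0("^", m, "_"), names(out), value = TRUE)
    s <- df[[paste0(m, "_sd")]]
    bad <- !is.na(s) & s == 0
    s[bad] <- NA
    n_zero <- n_zero + sum(bad)
    for (wv in wins) out[[wv]] <- out[[wv]] / s
  }
  res <- pheno_table(out, "continuous")
  rownames(res) <- rownames(pa)
  attr(res, "standardize_log") <- list(zero_sd_entries = n_zero)
  res
}

#' Principal component analysis of questionnaire items
#'
#' PCA on column-standardized (z-scored) items — the correlation-matrix
#' convention, appropriate because items sit on heterogeneous response
#' scales.  Signs are fixed so that each loading column's largest-magnitude
#' entry is positive, making results reproducible across runs and platforms.
#'
#' @param items a complete (imputed) `pheno_table` or numeric matrix.
#' @param scale. standardize columns before decomposition (default `TRUE`).
#' @return An object of class `pca_result`: list with `loadings` (variables x
#'   components, orthonormal columns), `scores` (subjects x components),
#'   `explained` (variance fractions, non-increasing), `n_retained`
#'   (initially all components).
#' @export
fit_pca <- function(items, scale. = TRUE) {
  X <- if (inherits(items, "pheno_table")) pt_matrix(items) else as.matrix(items)
  if (anyNA(X)) stop("PCA requires a complete table; impute first")
  if (ncol(X) > nrow(X)) stop("more variables than subjects")
  constant <- apply(X, 2, stats::sd) == 0
  if (any(constant)) stop("constant column(s): ", paste(colnames(X)[constant], collapse = ", "))
  p <- stats::prcomp(X, center = TRUE, scale. = scale.)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(p$rotation, 2, flip, `*`)
  scores <- sweep(p$x, 2, flip, `*`)
  expl <- p$sdev^2 / sum(p$sdev^2)
  structure(list(loadings = rot, scores = scores, explained = expl,
                 n_retained = ncol(rot)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components over %d variables; %d retained (%.1f%% variance)\n",
              ncol(x$loadings), nrow(x$loadings), x$n_retained,
              100 * sum(x$explained[seq_len(x$n_retained)])))
  invisible(x)
}

#' Retain leading components by cumulative explained variance
#'
#' Keeps the smallest leading set of components whose cumulative explained
#' variance *strictly* exceeds `cum_var` (always at least one component).
#'
#' @param res a `pca_result`.
#' @param cum_var cumulative-variance threshold (default 0.50).
#' @return The `pca_result` with `n_retained` set and `scores`/`loadings`
#'   trimmed to the retained set.
#' @export
retain_components <- function(res, cum_var = 0.50) {
  cum <- cumsum(res$explained)
  k <- which(cum > cum_var)[1]
  if (is.na(k)) k <- length(res$explained)
  k <- max(1L, k)
  res$n_retained <- k
  res$loadings <- res$loadings[, seq_len(k), drop = FALSE]
  res$scores <- res$scores[, seq_len(k), drop = FALSE]
  res
}

#' Pairwise correlations between component scores and activity measures
#'
#' Pearson correlation and two-sided p-value for every (component x activity
#' measure) pair, with Benjamini–Hochberg adjustment across the full grid as
#' one family.  Pairs involving a zero-variance column are reported as `NA`
#' and excluded from the FDR family (logged).
#'
#' @param scores a `pca_result` (its retained scores are used) or a numeric
#'   matrix of per-subject scores.
#' @param pa a `pheno_table` of standardized activity measures (rows aligned
#'   with the score rows).
#' @param q FDR level for the significance flags (default 0.05).
#' @return An object of class `correlation_grid`: list with matrices `r`,
#'   `p`, `p_fdr`, logical `significant`, and the family size `m`.
#' @export
correlate_blocks <- function(scores, pa, q = 0.05) {
  S <- if (inherits(scores, "pca_result")) {
    scores$scores[, seq_len(scores$n_retained), drop = FALSE]
  } else as.matrix(scores)
  X <- pt_matrix(pa)
  if (nrow(S) != nrow(X)) stop("subject counts differ")
  n <- nrow(S)
  r <- matrix(NA_real_, ncol(S), ncol(X),
              dimnames = list(colnames(S), colnames(X)))
  pv <- r
  for (i in seq_len(ncol(S))) {
    for (j in seq_len(ncol(X))) {
      ok <- stats::complete.cases(S[, i], X[, j])
      si <- S[ok, i]; xj <- X[ok, j]
      if (stats::sd(si) == 0 || stats::sd(xj) == 0 || sum(ok) < 3) next
      rr <- stats::cor(si, xj)
      tt <- rr * sqrt((sum(ok) - 2) / max(1e-300, 1 - rr^2))
      r[i, j] <- rr
      pv[i, j] <- 2 * stats::pt(-abs(tt), sum(ok) - 2)
    }
  }
  fam <- !is.na(pv)
  p_fdr <- pv
  p_fdr[fam] <- stats::p.adjust(pv[fam], method = "BH")
  structure(list(r = r, p = pv, p_fdr = p_fdr,
                 significant = !is.na(p_fdr) & p_fdr <= q,
                 m = sum(fam), q = q,
                 n_undefined = sum(!fam)),
            class = "correlation_grid")
}

#' @export
print.correlation_grid <- function(x, ...) {
  cat(sprintf("<correlation_grid> %d x %d pairs, family of %d tests, %d significant at q = %.2f\n",
              nrow(x$r), ncol(x$r), x$m, sum(x$significant), x$q))
  invisible(x)
}

#' Export a correlation grid as TSV
#'
#' Rows are activity measures, columns the components, mirroring the
#' printed-table layout; significant entries carry a trailing `*`.
#'
#' @param grid a `correlation_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correlation_grid <- function(grid, path) {
  vals <- t(grid$r)
  star <- t(grid$significant)
  txt <- matrix(sprintf("%.2f%s", vals, ifelse(star, "*", "")),
                nrow(vals), dimnames = dimnames(vals))
  txt[is.na(t(grid$r))] <- "NA"
  df <- data.frame(measure = rownames(txt), txt, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
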