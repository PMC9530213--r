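#' Wrap a correlation matrix as a genetic-covariance object
#'
#' Convenience constructor for structural modelling of a known (e.g. exactly
#' specified) genetic correlation matrix without LDSC estimation.  With no
#' sampling covariance the DWLS weights default to 1.
#'
#' @param R symmetric genetic correlation matrix with unit diagonal.
#' @param V optional sampling covariance of the lower-triangle off-diagonal
#'   elements (column-major order), with matching row/col names `"a:b"`.
#' @param h2 optional heritabilities (default 1, i.e. already standardized).
#' @return A `genetic_covariance` object.
#' @export
as_genetic_covariance <- function(R, V = NULL, h2 = NULL) {
  R <- as.matrix(R)
  labels <- rownames(R)
  if (is.null(labels)) {
    labels <- paste0("trait", seq_len(ncol(R)))
    dimnames(R) <- list(labels, labels)
  }
  if (is.null(h2)) h2 <- stats::setNames(rep(1, ncol(R)), labels)
  d <- sqrt(h2)
  S <- R * tcrossprod(d)
  structure(list(S = S, R = R, V = V, V_rg = V, h2 = h2,
                 h2_se = stats::setNames(rep(NA_real_, ncol(R)), labels),
                 pairs = NULL, labels = labels),
            class = "genetic_covariance")
}

# names and positions of lower-triangle off-diagonal elements of R[sel, sel]
pair_index <- function(labels) {
  k <- length(labels)
  ii <- which(lower.tri(matrix(0, k, k)), arr.ind = TRUE)
  ii <- ii[order(ii[, 2], ii[, 1]), , drop = FALSE]
  data.frame(row = ii[, 1], col = ii[, 2],
             name = paste(labels[ii[, 2]], labels[ii[, 1]], sep = ":"),
             stringsAsFactors = FALSE)
}

# extract the sampling covariance of the requested elements; weights fall
# back to 1 when V (or the element) is unavailable
subset_V <- function(gc, names_needed) {
  Vr <- if (!is.null(gc$V_rg)) gc$V_rg else gc$V
  if (is.null(Vr)) return(NULL)
  have <- rownames(Vr)
  alt <- vapply(strsplit(names_needed, ":"), function(ab)
    paste(rev(ab), collapse = ":"), character(1))
  pick <- ifelse(names_needed %in% have, names_needed,
                 ifelse(alt %in% have, alt, NA))
  if (anyNA(pick)) return(NULL)
  Vr[pick, pick, drop = FALSE]
}

# scaled test statistic of a DWLS fit: T_raw * df / tr(U V); falls back to
# the raw statistic when V is unavailable
scaled_chisq <- function(e, W, Delta, V, df) {
  T_raw <- sum(W * e^2)
  if (df <= 0) return(list(chisq = 0, df = df))
  if (is.null(V)) return(list(chisq = T_raw, df = df))
  Wm <- diag(W, length(W))
  U <- if (is.null(Delta)) Wm else {
    WD <- Wm %*% Delta
    Wm - WD %*% solve(crossprod(Delta, WD), t(WD))
  }
  tr <- sum(diag(U %*% V))
  list(chisq = T_raw * df / max(tr, 1e-12), df = df)
}

#' One-common-factor genomic structural equation model
#'
#' Fits a single latent factor to the genetic correlation matrix of the
#' chosen indicators by diagonally weighted least squares: minimizing
#' \eqn{\sum_{i<j} w_{ij} (r_{ij} - \lambda_i\lambda_j)^2} with weights
#' \eqn{w_{ij} = 1/Var(\hat r_{ij})} from the block jackknife (1 when
#' unavailable).  Residual variances are \eqn{1 - \lambda_i^2}; loadings are
#' bounded to `[-1, 1]` and a boundary solution (Heywood case) is flagged.
#' The model chi-square is sandwich-scaled against the full sampling
#' covariance `V`; CFI is computed against the independence model (all
#' correlations zero) and reported clamped to `[0, 1]` with the raw value
#' retained; SRMR averages squared standardized residuals over the lower
#' triangle including the (identically zero) diagonal.  Optimization starts
#' from five deterministic loading grids and keeps the best discrepancy.
#' The sign convention fixes the first indicator's loading positive.
#'
#' @param gc a `genetic_covariance`.
#' @param indicators character vector of >= 3 phenotype labels.
#' @return An object of class `factor_model`: `loadings`, `residuals`
#'   (variances), `chisq`, `df`, `cfi`, `cfi_raw`, `srmr`, `heywood`,
#'   `discrepancy`.
#' @export
fit_common_factor <- function(gc, indicators = gc$labels) {
  if (length(indicators) < 3) stop("need >= 3 indicators for identification")
  if (!all(indicators %in% gc$labels)) stop("unknown indicator label")
  R <- gc$R[indicators, indicators]
  if (anyNA(R)) stop("masked genetic correlations among the indicators")
  px <- pair_index(indicators)
  s <- R[cbind(px$row, px$col)]
  Vsub <- subset_V(gc, px$name)
  w <- if (is.null(Vsub)) rep(1, length(s)) else 1 / pmax(diag(Vsub), 1e-10)
  q <- length(indicators)

  obj <- function(lam) {
    imp <- lam[px$row] * lam[px$col]
    sum(w * (s - imp)^2)
  }
  gr <- function(lam) {
    imp <- lam[px$row] * lam[px$col]
    e <- -2 * w * (s - imp)
    g <- numeric(q)
    for (t in seq_len(q)) {
      g[t] <- sum(e[px$row == t] * lam[px$col[px$row == t]]) +
        sum(e[px$col == t] * lam[px$row[px$col == t]])
    }
    g
  }
  starts <- list(rep(0.3, q), rep(0.5, q), rep(0.7, q),
                 sign(R[, 1] + (R[, 1] == 0)) * 0.5,
                 sqrt(pmin(abs(R[, 1] + diag(q)[, 1] * 0), 1)) *
                   sign(R[, 1] + (R[, 1] == 0)))
  best <- NULL
  for (s0 in starts) {
    s0[1] <- abs(s0[1])
    fit <- stats::nlminb(s0, obj, gr, lower = rep(-1, q), upper = rep(1, q),
                         control = list(rel.tol = 1e-14, iter.max = 500))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  # nlminb's singular/relative-convergence codes are acceptable solutions
  # (common at bound constraints); only a hit iteration limit is a failure
  if (grepl("iteration limit|evaluation limit", best$message)) {
    stop("common-factor optimization failed to converge: ", best$message)
  }
  lam <- best$par
  if (lam[1] < 0) lam <- -lam
  heywood <- any(abs(lam) > 1 - 1e-6)
  if (heywood) warning("Heywood case: residual variance bounded at 0", call. = FALSE)
  names(lam) <- indicators

  imp <- lam[px$row] * lam[px$col]
  e <- s - imp
  Delta <- matrix(0, length(s), q)
  for (t in seq_len(q)) {
    Delta[px$row == t, t] <- lam[px$col[px$row == t]]
    Delta[px$col == t, t] <- Delta[px$col == t, t] + lam[px$row[px$col == t]]
  }
  df_m <- length(s) - q
  ch_m <- scaled_chisq(e, w, Delta, Vsub, df_m)
  ch_0 <- scaled_chisq(s, w, NULL, Vsub, length(s))
  if (is.null(Vsub)) {
    # population matrix (no sampling covariance): CFI as a plain discrepancy
    # ratio against the independence model
    cfi_raw <- 1 - sum(w * e^2) / max(sum(w * s^2), 1e-12)
  } else {
    num <- max(0, ch_m$chisq - max(0, ch_m$df))
    den <- max(ch_0$chisq - ch_0$df, 1e-12)
    cfi_raw <- 1 - num / den
  }
  srmr <- sqrt(sum(e^2) / (length(s) + q))  # diagonal residuals are 0

  structure(list(loadings = lam, residuals = 1 - lam^2,
                 chisq = ch_m$chisq, df = ch_m$df,
                 baseline_chisq = ch_0$chisq, baseline_df = ch_0$df,
                 cfi = min(max(cfi_raw, 0), 1), cfi_raw = cfi_raw,
                 srmr = srmr, heywood = heywood,
                 discrepancy = best$objective, indicators = indicators),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat("<factor_model> one common factor\n")
  print(round(x$loadings, 3))
  cat(sprintf("  CFI = %.3f  SRMR = %.4f  chisq(%d) = %.2f\n",
              x$cfi, x$srmr, x$df, x$chisq))
  invisible(x)
}

#' Genetic correlation between a latent factor and an external phenotype
#'
#' Joint DWLS model: one common factor over the indicators plus a freely
#' correlated external phenotype; the factor–external genetic correlation
#' \eqn{\phi} is the estimand (implied indicator–external correlations are
#' \eqn{\lambda_i \phi}).  Its standard error comes from the sandwich
#' estimator \eqn{(\Delta' W \Delta)^{-1} \Delta' W V W \Delta
#' (\Delta' W \Delta)^{-1}} evaluated at the solution; the p-value is
#' two-sided normal.
#'
#' @param gc a `genetic_covariance` containing both indicators and external.
#' @param indicators factor indicator labels.
#' @param external single external phenotype label.
#' @return List with `rg`, `se`, `p`, `loadings`, and the underlying
#'   `factor_model` of the indicators.
#' @export
factor_external_rg <- function(gc, indicators, external) {
  stopifnot(length(external) == 1, external %in% gc$labels)
  if (external %in% indicators) stop("external phenotype cannot be an indicator")
  q <- length(indicators)
  labs <- c(indicators, external)
  R <- gc$R[labs, labs]
  px <- pair_index(labs)
  s <- R[cbind(px$row, px$col)]
  Vsub <- subset_V(gc, px$name)
  w <- if (is.null(Vsub)) rep(1, length(s)) else 1 / pmax(diag(Vsub), 1e-10)
  is_ext <- px$row == q + 1 | px$col == q + 1
  other <- function(rr, cc) ifelse(rr == q + 1, cc, rr)
  ext_ind <- other(px$row, px$col)[is_ext]

  obj <- function(th) {
    lam <- th[seq_len(q)]; phi <- th[q + 1]
    imp <- ifelse(is_ext, lam[pmin(other(px$row, px$col), q)] * phi,
                  lam[pmin(px$row, q)] * lam[pmin(px$col, q)])
    sum(w * (s - imp)^2)
  }
  base <- fit_common_factor(gc, indicators)
  ext_r <- R[q + 1, seq_len(q)]
  phi0 <- sum(ext_r * base$loadings) / max(sum(base$loadings^2), 1e-8)
  starts <- list(c(base$loadings, max(min(phi0, 1), -1)),
                 c(base$loadings, 0.2), c(base$loadings, -0.2),
                 c(rep(0.5, q), 0), c(rep(0.3, q), 0.1))
  best <- NULL
  for (s0 in starts) {
    fit <- stats::nlminb(s0, obj, lower = rep(-1, q + 1),
                         upper = rep(1, q + 1),
                         control = list(rel.tol = 1e-14, iter.max = 500))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  th <- best$par
  lam <- th[seq_len(q)]; phi <- th[q + 1]
  if (lam[1] < 0) { lam <- -lam; phi <- -phi }

  # sandwich SE
  Delta <- matrix(0, length(s), q + 1)
  for (t in seq_len(q)) {
    in_rows <- !is_ext & px$row == t
    in_cols <- !is_ext & px$col == t
    Delta[in_rows, t] <- lam[px$col[in_rows]]
    Delta[in_cols, t] <- Delta[in_cols, t] + lam[px$row[in_cols]]
    here <- is_ext & other(px$row, px$col) == t
    Delta[here, t] <- phi
  }
  Delta[is_ext, q + 1] <- lam[ext_ind]
  se <- NA_real_
  if (!is.null(Vsub)) {
    Wm <- diag(w, length(w))
    bread <- solve(crossprod(Delta, Wm %*% Delta))
    meat <- crossprod(Delta, Wm %*% Vsub %*% Wm %*% Delta)
    covth <- bread %*% meat %*% bread
    se <- sqrt(covth[q + 1, q + 1])
  }
  list(rg = unname(phi), se = se,
       p = if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(phi / se)),
       loadings = stats::setNames(lam, indicators), factor_model = base)
}
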