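#' Residualize a block on confounds
#'
#' Replaces every column by its residual from a least-squares projection onto
#' `[intercept | confounds]`.  Rank-deficient confound columns are dropped
#' with a warning.
#'
#' @param data numeric matrix or `pheno_table`.
#' @param confounds numeric matrix or `pheno_table` of dummy-coded, complete
#'   confounds; `NULL` mean-centers only.
#' @return Residualized numeric matrix (same dimnames).
#' @export
residualize <- function(data, confounds = NULL) {
  D <- if (inherits(data, "pheno_table")) pt_matrix(data) else as.matrix(data)
  if (is.null(confounds)) return(scale(D, center = TRUE, scale = FALSE))
  C <- if (inherits(confounds, "pheno_table")) pt_matrix(confounds) else as.matrix(confounds)
  if (anyNA(C)) stop("confounds must be complete")
  if (nrow(C) != nrow(D)) stop("row counts differ")
  X <- cbind(1, C)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    warning("confound matrix rank-deficient; dropping ",
            ncol(X) - qrx$rank, " dependent column(s)", call. = FALSE)
  }
  R <- qr.resid(qrx, D)
  dimnames(R) <- dimnames(D)
  R
}

#' Huh–Jhun reduction of residualized data
#'
#' Projects residualized data onto an orthonormal basis of the space
#' orthogonal to the confounds, yielding `n - rank` exchangeable rows.
#' Optional honesty device for permutation inference after residualization
#' (default off throughout the package).
#'
#' @param data residualized numeric matrix.
#' @param confounds the confound matrix the data were residualized on.
#' @return Matrix with `n - rank([1 | confounds])` rows.
#' @export
huh_jhun_reduce <- function(data, confounds) {
  X <- cbind(1, as.matrix(confounds))
  qrx <- qr(X)
  n <- nrow(X)
  Qfull <- qr.Q(qrx, complete = TRUE)
  Q2 <- Qfull[, (qrx$rank + 1L):n, drop = FALSE]
  crossprod(Q2, as.matrix(data))
}

#' Canonical correlation analysis
#'
#' Standard CCA via QR orthogonalization of each (centered) block and SVD of
#' the cross-product of the orthonormal bases — numerically the whitened
#' cross-covariance.  Canonical variates are scaled to unit variance;
#' loadings are the correlations between the original variables and their
#' block's variates.
#'
#' @param Y numeric matrix or `pheno_table` (e.g. brain measures), already
#'   residualized on confounds.
#' @param X second block (e.g. behavioural measures), residualized likewise.
#' @param tag optional model tag (e.g. `"simple_mh"`).
#' @return An object of class `cca_model`: weights `A`, `B`; variates `U`,
#'   `V`; canonical correlations `cor` (descending); loadings `loadings_Y`
#'   (= cor(Y, U)) and `loadings_X` (= cor(X, V)); permutation p-values `p`
#'   are filled in by [permute_inference()].
#' @export
fit_cca <- function(Y, X, tag = NULL) {
  Y <- if (inherits(Y, "pheno_table")) pt_matrix(Y) else as.matrix(Y)
  X <- if (inherits(X, "pheno_table")) pt_matrix(X) else as.matrix(X)
  n <- nrow(Y)
  if (nrow(X) != n) stop("row counts differ")
  p <- ncol(Y); q <- ncol(X)
  if (n <= p + q) stop("need more subjects than total variables (n > p + q)")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qy <- qr(Yc); qx <- qr(Xc)
  if (qy$rank < p || qx$rank < q) {
    stop("within-block singularity; reduce the rank of the offending block")
  }
  Qy <- qr.Q(qy); Qx <- qr.Q(qx)
  # full SVD: complete rotations of BOTH spaces are needed so the step-down
  # permutation scheme sees the residual dimensions beyond min(p, q)
  sv <- svd(crossprod(Qy, Qx), nu = p, nv = q)
  K <- min(p, q)
  r <- pmin(pmax(sv$d[seq_len(K)], 0), 1)
  # rotated orthonormal bases: first K columns are the canonical directions
  Ytil <- Qy %*% sv$u
  Xtil <- Qx %*% sv$v
  U <- Ytil[, seq_len(K), drop = FALSE] * sqrt(n - 1)
  V <- Xtil[, seq_len(K), drop = FALSE] * sqrt(n - 1)
  A <- qr.coef(qy, U)  # pivot-safe: U lies in the column space of Yc
  B <- qr.coef(qx, V)
  loadY <- stats::cor(Y, U)
  loadX <- stats::cor(X, V)
  colnames(U) <- colnames(V) <- paste0("CV", seq_len(K))
  colnames(loadY) <- colnames(loadX) <- colnames(U)
  structure(list(A = A, B = B, U = U, V = V, cor = r,
                 loadings_Y = loadY, loadings_X = loadX,
                 p = rep(NA_real_, K), n = n, tag = tag,
                 Ytil = Ytil, Xtil = Xtil),
            class = "cca_model")
}

#' @export
print.cca_model <- function(x, ...) {
  cat(sprintf("<cca_model%s> %d variate pairs, n = %d\n",
              if (is.null(x$tag)) "" else paste0(": ", x$tag),
              length(x$cor), x$n))
  k <- seq_len(min(5, length(x$cor)))
  cat("  r:", sprintf("%.3f", x$cor[k]), if (length(x$cor) > 5) "...", "\n")
  if (!all(is.na(x$p))) cat("  p:", sprintf("%.3f", x$p[k]), "\n")
  invisible(x)
}

wilks_stat <- function(r) -sum(log1p(-pmin(r, 1 - 1e-12)^2))

#' Permutation inference for canonical variates
#'
#' Rows of the X block are permuted relative to Y.  For variate `k` the test
#' statistic is a step-down Wilks-type product over variates `k..K`, computed
#' after removing the preceding `k - 1` estimated canonical directions from
#' both sides (closure principle), so later p-values are valid conditionally
#' on earlier ones.  P-values use the add-one rule
#' `(count >= observed + 1) / (n_perm + 1)` and are forced monotone
#' non-decreasing via a cumulative maximum.
#'
#' @param model a `cca_model` from [fit_cca()].
#' @param n_perm number of permutations (default 1000; below 100 the
#'   resolution is poor and a warning is raised).
#' @param seed integer seed for the permutation stream.
#' @return The model with `p` (per-variate p-values) and
#'   `perm_stats` (matrix of permuted statistics, variates x permutations)
#'   filled in.
#' @export
permute_inference <- function(model, n_perm = 1000, seed = 1L) {
  stopifnot(inherits(model, "cca_model"))
  if (n_perm < 100) warning("n_perm < 100: p-value resolution is coarse", call. = FALSE)
  Ytil <- model$Ytil; Xtil <- model$Xtil
  n <- nrow(Ytil); p <- ncol(Ytil); q <- ncol(Xtil)
  K <- length(model$cor)
  obs <- vapply(seq_len(K), function(k) wilks_stat(model$cor[k:K]), numeric(1))
  set.seed(seed)
  exceed <- integer(K)
  perm_stats <- matrix(NA_real_, K, n_perm)
  for (b in seq_len(n_perm)) {
    pi_b <- sample.int(n)
    Mfull <- crossprod(Ytil, Xtil[pi_b, , drop = FALSE])
    for (k in seq_len(K)) {
      d <- svd(Mfull[k:p, k:q, drop = FALSE], nu = 0, nv = 0)$d
      perm_stats[k, b] <- wilks_stat(pmin(pmax(d, 0), 1))
    }
  }
  pvals <- (rowSums(perm_stats >= obs) + 1) / (n_perm + 1)
  model$p <- cummax(pvals)
  model$perm_stats <- perm_stats
  model$n_perm <- n_perm
  model
}

#' Unique-variance CCA model
#'
#' The "unique" contrast: the other behavioural block is appended to the
#' confound set, so the model captures only variance not shared with it.
#' Both the Y block and the target X block are residualized on the expanded
#' set by default; `partial = "y-only"` residualizes only the Y block on the
#' other behavioural set (the target block still loses the ordinary
#' confounds).
#'
#' @param Y brain block (not yet residualized).
#' @param X_target behavioural block of interest.
#' @param X_other the other behavioural block, treated as covariates.
#' @param confounds dummy-coded confound matrix (or `NULL`).
#' @param n_perm,seed passed to [permute_inference()].
#' @param partial `"both"` or `"y-only"`.
#' @param tag model tag.
#' @return A `cca_model` with permutation p-values filled in.
#' @export
unique_model <- function(Y, X_target, X_other, confounds = NULL,
                         n_perm = 1000, seed = 1L,
                         partial = c("both", "y-only"), tag = "unique") {
  partial <- match.arg(partial)
  Xo <- if (inherits(X_other, "pheno_table")) pt_matrix(X_other) else as.matrix(X_other)
  if (ncol(Xo) == 0) Xo <- NULL  # empty covariate set: reduces to the simple model
  Cm <- if (is.null(confounds)) NULL else {
    if (inherits(confounds, "pheno_table")) pt_matrix(confounds) else as.matrix(confounds)
  }
  Cb <- cbind(Cm, Xo)
  if (is.null(Cb) || ncol(Cb) == 0) Cb <- NULL
  if (is.null(Cb)) {
    m <- fit_cca(residualize(Y, NULL), residualize(X_target, NULL), tag = tag)
    return(permute_inference(m, n_perm = n_perm, seed = seed))
  }
  n <- nrow(Cb)
  if (ncol(Cb) > n / 10) {
    warning("expanded confound set exceeds n/10 columns", call. = FALSE)
  }
  Yr <- residualize(Y, Cb)
  Xr <- if (partial == "both") residualize(X_target, Cb)
        else residualize(X_target, confounds)
  m <- fit_cca(Yr, Xr, tag = tag)
  permute_inference(m, n_perm = n_perm, seed = seed)
}

#' Permutation test of canonical loadings
#'
#' For each permutation the CCA is refit on permuted data and every Y-side
#' variable's loading magnitude on each tested variate is recorded.  Each
#' variable's null distribution pools permuted loadings *across* the tested
#' (significant) variates — the correction for the number of significant
#' variates within a model.  Observed loadings are compared as magnitudes
#' (canonical signs are arbitrary), with the add-one p-value rule.
#'
#' @param model a `cca_model` with permutation p-values (or explicit
#'   `variates`).
#' @param Y the original Y-side data matrix the model was fit on (needed to
#'   compute loadings of the permuted fits).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param variates integer vector of variates to test; default: variates
#'   significant at `alpha`.
#' @param alpha significance level used both to select variates and to flag
#'   loadings.
#' @return An object of class `loading_nulls`: list with `p` (variables x
#'   tested variates), `significant` flags, `observed` loadings, `null`
#'   (pooled null magnitudes per variable), `variates`.  Empty (zero-column)
#'   result if no variate is significant.
#' @export
loading_significance <- function(model, Y, n_perm = 1000, seed = 1L,
                                 variates = NULL, alpha = 0.05) {
  stopifnot(inherits(model, "cca_model"))
  Y <- if (inherits(Y, "pheno_table")) pt_matrix(Y) else as.matrix(Y)
  if (is.null(variates)) {
    if (all(is.na(model$p))) stop("run permute_inference() first or give `variates`")
    variates <- which(model$p <= alpha)
  }
  vars <- rownames(model$loadings_Y)
  if (is.null(vars)) vars <- colnames(Y)
  if (!length(variates)) {
    return(structure(list(p = matrix(NA_real_, nrow(model$loadings_Y), 0,
                                     dimnames = list(vars, NULL)),
                          significant = NULL, observed = NULL,
                          null = NULL, variates = integer(0),
                          note = "no significant variates"),
                     class = "loading_nulls"))
  }
  Ytil <- model$Ytil; Xtil <- model$Xtil
  n <- nrow(Ytil); p <- ncol(Ytil); q <- ncol(Xtil)
  nv <- length(variates)
  # unit-norm centered Y columns: correlations become plain cross-products
  Yn <- scale(Y, center = TRUE, scale = FALSE)
  Yn <- sweep(Yn, 2, sqrt(colSums(Yn^2)), `/`)
  set.seed(seed)
  null_pool <- matrix(NA_real_, ncol(Y), n_perm * nv)
  for (b in seq_len(n_perm)) {
    pi_b <- sample.int(n)
    sv <- svd(crossprod(Ytil, Xtil[pi_b, , drop = FALSE]))
    Uperm <- Ytil %*% sv$u[, variates, drop = FALSE]  # unit-norm columns
    null_pool[, (b - 1) * nv + seq_len(nv)] <- abs(crossprod(Yn, Uperm))
  }
  obs <- abs(model$loadings_Y[, variates, drop = FALSE])
  pmat <- matrix(NA_real_, nrow(obs), ncol(obs),
                 dimnames = list(vars, colnames(model$loadings_Y)[variates]))
  for (j in seq_len(nrow(obs))) {
    for (k in seq_len(ncol(obs))) {
      pmat[j, k] <- (sum(null_pool[j, ] >= obs[j, k]) + 1) /
        (ncol(null_pool) + 1)
    }
  }
  structure(list(p = pmat, significant = pmat <= alpha, observed = obs,
                 null = null_pool, variates = variates),
            class = "loading_nulls")
}

#' Match canonical variates across models
#'
#' Computes absolute Pearson correlations between all pairs of Y-side
#' canonical variates (`U` columns) of two models fitted on the same
#' subjects, and greedily pairs variates by descending `|cor|` (ties broken
#' by variate index).  The sign of each match is recorded so loadings can be
#' aligned for display.
#'
#' @param model_a,model_b `cca_model` objects sharing subjects.
#' @return data.frame with columns `variate_a`, `variate_b`, `cor`
#'   (absolute), `sign`.
#' @export
match_variates <- function(model_a, model_b) {
  Ua <- model_a$U; Ub <- model_b$U
  if (nrow(Ua) != nrow(Ub)) stop("models do not share subjects")
  C <- stats::cor(Ua, Ub)
  Ka <- ncol(Ua); Kb <- ncol(Ub)
  A <- abs(C)
  out <- data.frame(variate_a = integer(0), variate_b = integer(0),
                    cor = numeric(0), sign = integer(0))
  for (s in seq_len(min(Ka, Kb))) {
    best <- which(A == max(A), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    out <- rbind(out, data.frame(variate_a = i, variate_b = j,
                                 cor = A[i, j], sign = sign(C[i, j])))
    A[i, ] <- -Inf; A[, j] <- -Inf
  }
  out[order(out$variate_a), ]
}
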