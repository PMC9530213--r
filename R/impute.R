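#' Imputation settings
#'
#' @param n_iterations chained-equation iterations; the final imputed value of
#'   a continuous/ordinal cell is the mean of its draws across all
#'   iterations, and of a categorical cell the modal level across iterations.
#' @param n_donors number of candidate donors `k` for predictive mean
#'   matching ("three or five" are conventional; 5 is the default here).
#' @param draw_coefficients if `FALSE`, the posterior draw of regression
#'   coefficients is disabled and predictions use the least-squares estimate
#'   (deterministic mode, used by the brute-force oracle tests).
#' @param seed integer seed.
#' @return An object of class `imputation_spec`.
#' @export
imputation_spec <- function(n_iterations = 20, n_donors = 5,
                            draw_coefficients = TRUE, seed = 1L) {
  if (n_donors < 1) stop("n_donors must be >= 1")
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  structure(list(n_iterations = as.integer(n_iterations),
                 n_donors = as.integer(n_donors),
                 draw_coefficients = isTRUE(draw_coefficients),
                 seed = as.integer(seed)),
            class = "imputation_spec")
}

#' Drop variables with excessive missingness
#'
#' Variables whose missing fraction *strictly* exceeds `max_missing` are
#' excluded (a variable missing exactly the threshold fraction is retained).
#'
#' @param table a `pheno_table`.
#' @param max_missing maximum tolerated missing fraction (default 0.30).
#' @return A list with `table` (the reduced `pheno_table`) and `dropped`
#'   (named numeric vector of the missing fractions of excluded variables).
#' @export
exclude_sparse_variables <- function(table, max_missing = 0.30) {
  if (ncol(table) == 0) stop("empty table")
  frac <- colMeans(missing_mask(table))
  drop <- frac > max_missing
  if (all(drop)) stop("all variables exceed the missingness threshold")
  list(table = pt_select(table, names(frac)[!drop]),
       dropped = frac[drop])
}

# Bayesian linear regression draw + donor matching for one variable.
# Returns imputed values (one per missing row), each an observed donor value.
pmm_draw <- function(y, X, mis, k, draw) {
  obs <- !mis
  Xo <- cbind(1, X[obs, , drop = FALSE])
  Xm <- cbind(1, X[mis, , drop = FALSE])
  qrx <- qr(Xo)
  if (qrx$rank < ncol(Xo)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    warning("rank-deficient predictor matrix; dropping ",
            ncol(Xo) - qrx$rank, " collinear predictor(s)", call. = FALSE)
    Xo <- Xo[, keep, drop = FALSE]
    Xm <- Xm[, keep, drop = FALSE]
    qrx <- qr(Xo)
  }
  beta <- qr.coef(qrx, y[obs])
  res <- y[obs] - Xo %*% beta
  df <- max(1L, length(res) - qrx$rank)
  if (draw) {
    sigma2 <- sum(res^2) / stats::rchisq(1, df)
    R <- qr.R(qrx)
    bstar <- beta + backsolve(R, stats::rnorm(ncol(Xo))) * sqrt(sigma2)
  } else bstar <- beta
  pred_obs <- drop(Xo %*% beta)
  pred_mis <- drop(Xm %*% bstar)

  ord <- order(pred_obs)
  po <- pred_obs[ord]
  yo <- y[obs][ord]
  n_obs <- length(po)
  vapply(pred_mis, function(pm) {
    pos <- findInterval(pm, po)
    lo <- max(1L, pos - k + 1L)
    hi <- min(n_obs, pos + k)
    cand <- lo:hi
    d <- abs(po[cand] - pm)
    sel <- cand[order(d, cand)][seq_len(min(k, length(cand)))]
    if (draw || k > 1) yo[sel[sample.int(length(sel), 1)]] else yo[sel[1]]
  }, numeric(1))
}

#' Predictive mean matching imputation (chained equations)
#'
#' For each incomplete continuous/ordinal variable, per iteration: a linear
#' regression of that variable on all other variables (their current
#' completed versions) is fitted on the originally observed rows;
#' coefficients are drawn from their approximate posterior (normal around the
#' estimate with a scaled chi-squared residual-variance draw); the `k`
#' observed rows whose predictions are closest to each missing row's
#' prediction form the donor pool, and one donor's *observed* value is copied
#' at random.  Visit order is ascending missingness; the initial fill draws
#' randomly from each variable's observed values.  The final imputed value is
#' the mean over all iterations' draws — so averaged ordinal items may be
#' non-integer, and downstream PCA consumes them as continuous.
#'
#' Observed entries are never altered.  Categorical columns are ignored here
#' (see [categorical_impute()]).
#'
#' @param table a `pheno_table` with numeric (continuous/ordinal) columns.
#' @param spec an [imputation_spec()].
#' @return The completed `pheno_table`; attribute `"impute_log"` records the
#'   per-variable missing counts, and `"draws"` the per-iteration draws for
#'   audit.
#' @export
pmm_impute <- function(table, spec = imputation_spec()) {
  kinds <- var_kinds(table)
  num_vars <- names(kinds)[kinds %in% c("continuous", "ordinal")]
  df <- as.data.frame(table)
  M <- missing_mask(table)[, num_vars, drop = FALSE]
  incomplete <- num_vars[colSums(M) > 0]
  if (!length(incomplete)) return(table)

  set.seed(spec$seed)
  work <- as.matrix(df[, num_vars, drop = FALSE])
  for (v in incomplete) {
    mis <- M[, v]
    n_complete <- sum(!mis)
    if (n_complete < spec$n_donors) {
      stop("variable ", v, " has fewer complete rows than donors requested")
    }
    work[mis, v] <- sample(work[!mis, v], sum(mis), replace = TRUE)
  }
  visit <- incomplete[order(colSums(M)[incomplete])]

  draws <- lapply(stats::setNames(visit, visit), function(v)
    matrix(NA_real_, sum(M[, v]), spec$n_iterations))
  for (it in seq_len(spec$n_iterations)) {
    for (v in visit) {
      mis <- M[, v]
      X <- work[, setdiff(num_vars, v), drop = FALSE]
      imp <- pmm_draw(df[[v]], X, mis, spec$n_donors, spec$draw_coefficients)
      work[mis, v] <- imp
      draws[[v]][, it] <- imp
    }
  }
  for (v in visit) {
    mis <- M[, v]
    df[[v]][mis] <- rowMeans(draws[[v]])
    df[[v]][!mis] <- as.data.frame(table)[[v]][!mis]
  }
  out <- pheno_table(df, kinds)
  rownames(out) <- rownames(table)
  attr(out, "impute_log") <- list(variables = visit,
                                  n_missing = colSums(M)[visit])
  attr(out, "draws") <- draws
  out
}

# Multinomial logistic regression by penalized maximum likelihood (softmax
# link, small ridge for stability).  Returns a probability-matrix predictor.
fit_multinomial <- function(X, y, ridge = 1e-6, maxit = 200) {
  lev <- levels(y)
  L <- length(lev)
  X1 <- cbind(1, X)
  P <- ncol(X1)
  Y <- outer(as.integer(y), seq_len(L), "==") * 1
  nll <- function(theta) {
    B <- cbind(0, matrix(theta, P, L - 1L))
    eta <- X1 %*% B
    eta <- eta - apply(eta, 1, max)
    logZ <- log(rowSums(exp(eta)))
    -sum(rowSums(Y * eta) - logZ) + ridge * sum(theta^2) / 2
  }
  grad <- function(theta) {
    B <- cbind(0, matrix(theta, P, L - 1L))
    eta <- X1 %*% B
    eta <- eta - apply(eta, 1, max)
    Pm <- exp(eta); Pm <- Pm / rowSums(Pm)
    G <- t(X1) %*% (Pm - Y)
    as.vector(G[, -1L]) + ridge * theta
  }
  fit <- stats::optim(rep(0, P * (L - 1L)), nll, grad, method = "BFGS",
                      control = list(maxit = maxit))
  B <- cbind(0, matrix(fit$par, P, L - 1L))
  function(Xnew) {
    eta <- cbind(1, Xnew) %*% B
    eta <- eta - apply(eta, 1, max)
    Pm <- exp(eta)
    Pm <- Pm / rowSums(Pm)
    colnames(Pm) <- lev
    Pm
  }
}

#' Multinomial imputation of categorical variables
#'
#' Per iteration, a multinomial logistic regression of each incomplete
#' categorical variable on the other (numeric-coded) variables is fitted on
#' the observed rows, and the imputed level is drawn from the predicted class
#' probabilities.  The final value is the level with the highest count across
#' iterations; ties are resolved by the variable's fixed level order (and
#' recorded in the log).  Levels absent from the training rows receive zero
#' probability.
#'
#' @param table a `pheno_table`; categorical columns may be factor or
#'   character, other columns must be complete (impute them first).
#' @param spec an [imputation_spec()].
#' @return The completed `pheno_table` with attribute `"impute_log"`.
#' @export
categorical_impute <- function(table, spec = imputation_spec()) {
  kinds <- var_kinds(table)
  cat_vars <- names(kinds)[kinds == "categorical"]
  df <- as.data.frame(table)
  for (v in cat_vars) df[[v]] <- factor(df[[v]])
  M <- is.na(df)
  incomplete <- cat_vars[colSums(M[, cat_vars, drop = FALSE]) > 0]
  if (!length(incomplete)) {
    out <- pheno_table(df, kinds); rownames(out) <- rownames(table)
    return(out)
  }
  set.seed(spec$seed + 1L)
  log <- list(ties = character(0))

  # numeric design from the other columns (categoricals one-hot on the fly)
  design_from <- function(cols, data) {
    mats <- lapply(cols, function(u) {
      x <- data[[u]]
      if (is.factor(x)) {
        lv <- levels(x)
        if (length(lv) < 2) return(NULL)
        m <- outer(as.integer(x), 2:length(lv), function(i, j) (i == j) * 1)
        colnames(m) <- paste(u, lv[-1], sep = "_")
        m
      } else matrix(x, ncol = 1, dimnames = list(NULL, u))
    })
    do.call(cbind, Filter(Negate(is.null), mats))
  }

  # initial fill
  work <- df
  for (v in incomplete) {
    mis <- M[, v]
    work[[v]][mis] <- sample(as.character(df[[v]][!mis]), sum(mis),
                             replace = TRUE)
  }
  counts <- lapply(stats::setNames(incomplete, incomplete), function(v) {
    matrix(0L, sum(M[, v]), nlevels(df[[v]]),
           dimnames = list(NULL, levels(df[[v]])))
  })
  for (it in seq_len(spec$n_iterations)) {
    for (v in incomplete) {
      mis <- M[, v]
      yobs <- droplevels(df[[v]][!mis])
      if (nlevels(yobs) < 2) {
        lev1 <- levels(yobs)
        work[[v]][mis] <- lev1
        counts[[v]][, lev1] <- counts[[v]][, lev1] + 1L
        next
      }
      X <- design_from(setdiff(names(df), v), work)
      pred <- fit_multinomial(X[!mis, , drop = FALSE], yobs)
      pm <- pred(X[mis, , drop = FALSE])
      lv <- colnames(pm)
      drawn <- apply(pm, 1, function(p) lv[sample.int(length(lv), 1, prob = p)])
      work[[v]][mis] <- drawn
      ii <- cbind(seq_len(sum(mis)), match(drawn, levels(df[[v]])))
      counts[[v]][ii] <- counts[[v]][ii] + 1L
    }
  }
  for (v in incomplete) {
    mis <- M[, v]
    cm <- counts[[v]]
    best <- apply(cm, 1, which.max)  # which.max = first max -> level order
    tie <- apply(cm, 1, function(r) sum(r == max(r)) > 1)
    if (any(tie)) {
      log$ties <- c(log$ties, sprintf("%s: %d tie(s) resolved by level order",
                                      v, sum(tie)))
    }
    df[[v]][mis] <- levels(df[[v]])[best]
  }
  out <- pheno_table(df, kinds)
  rownames(out) <- rownames(table)
  attr(out, "impute_log") <- log
  out
}

#' Dummy-code categorical variables
#'
#' Each `m`-level categorical variable becomes `m - 1` indicator columns
#' against its reference (first) level.  Requires a complete table.
#'
#' @param table a `pheno_table` with no missing entries.
#' @return A `pheno_table` whose columns are all continuous.
#' @export
dummy_code <- function(table) {
  if (anyNA(as.data.frame(table))) stop("impute before dummy coding")
  kinds <- var_kinds(table)
  df <- as.data.frame(table)
  pieces <- lapply(names(df), function(v) {
    if (kinds[[v]] != "categorical") return(df[v])
    x <- factor(df[[v]])
    lv <- levels(x)
    if (length(lv) < 2) return(NULL)  # constant variable carries no contrast
    out <- as.data.frame(outer(as.integer(x), 2:length(lv),
                               function(i, j) (i == j) * 1))
    names(out) <- paste(v, lv[-1], sep = "_")
    out
  })
  res <- do.call(cbind, Filter(Negate(is.null), pieces))
  rownames(res) <- rownames(table)
  pheno_table(res, "continuous")
}
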