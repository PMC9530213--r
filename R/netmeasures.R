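#' Subnetwork amplitudes from component timeseries
#'
#' The amplitude of a resting-state component is the sample standard
#' deviation of its timeseries (denominator `n - 1`), capturing the
#' within-network signal-fluctuation magnitude.  A constant timeseries has
#' amplitude 0.
#'
#' @param ts numeric matrix, timepoints x components (no missing values).
#' @return Named numeric vector of non-negative amplitudes, one per column.
#' @export
amplitude <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2) stop("need at least 2 timepoints")
  if (anyNA(ts)) stop("timeseries must not contain missing values")
  apply(ts, 2, stats::sd)
}

#' Ridge-regularized partial-correlation edges
#'
#' Computes partial correlations between components from the inverse of the
#' ridge-regularized correlation matrix, `solve(cor(ts) + ridge * I)`,
#' normalized as \eqn{-p_{ij}/\sqrt{p_{ii} p_{jj}}}.  Partialling is always
#' over *all* components; `select` restricts which component pairs are
#' returned afterwards (mirroring selecting 7 networks of interest out of the
#' 55 signal components that enter the precision matrix).  The ridge acts on
#' the correlation (not covariance) matrix, making the regularization
#' scale-free; this choice is recorded in the output's `"ridge"` attribute.
#'
#' @param ts numeric matrix, timepoints x components.
#' @param ridge non-negative regularization constant added to the diagonal of
#'   the correlation matrix.  With `ridge = 0` and a well-conditioned
#'   covariance the result equals classical (regression-residual) partial
#'   correlations.
#' @param select integer or character vector naming the components whose
#'   pairwise edges are returned (default: all).
#' @return Named numeric vector of length `choose(length(select), 2)` with
#'   names `"<a>-<b>"`; attributes `ridge` and `select` record the settings.
#' @export
partial_edges <- function(ts, ridge = 0.5, select = NULL) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2) stop("need at least 2 timepoints")
  if (ridge < 0) stop("ridge must be >= 0")
  C <- stats::cor(ts)
  if (anyNA(C)) stop("constant component column: correlation undefined")
  Creg <- C + diag(ridge, ncol(C))
  P <- tryCatch(solve(Creg), error = function(e) {
    stop("singular covariance; use ridge > 0")
  })
  d <- sqrt(diag(P))
  R <- -P / tcrossprod(d)
  diag(R) <- 1
  if (is.null(select)) select <- seq_len(ncol(ts))
  if (is.character(select)) select <- match(select, colnames(ts))
  if (anyNA(select)) stop("unknown component in `select`")
  labs <- colnames(ts)
  if (is.null(labs)) labs <- paste0("c", seq_len(ncol(ts)))
  pairs <- utils::combn(select, 2)
  out <- R[t(pairs)]
  names(out) <- apply(pairs, 2, function(ii) paste(labs[ii], collapse = "-"))
  structure(out, ridge = ridge, select = labs[select])
}

#' Network measures for one subject
#'
#' Convenience wrapper combining [amplitude()] (for the selected components)
#' and [partial_edges()] (partialled over all components) into the 28-measure
#' layout used downstream: `choose(k, 2)` edges followed by `k` amplitudes.
#'
#' @inheritParams partial_edges
#' @return Named numeric vector of edges then amplitudes.
#' @export
network_measures <- function(ts, ridge = 0.5, select = NULL) {
  ts <- as.matrix(ts)
  if (is.null(select)) select <- seq_len(ncol(ts))
  if (is.character(select)) select <- match(select, colnames(ts))
  edges <- partial_edges(ts, ridge = ridge, select = select)
  amps <- amplitude(ts[, select, drop = FALSE])
  names(amps) <- paste0("amp_", names(amps))
  c(edges, amps)
}

#' Read a per-subject timeseries file
#'
#' Tab-separated text, timepoints x components, optional header row of
#' component labels.
#'
#' @param path file path.
#' @param header whether the first line holds component labels.
#' @return Numeric matrix.
#' @export
read_timeseries <- function(path, header = TRUE) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = header))
  storage.mode(m) <- "double"
  m
}
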