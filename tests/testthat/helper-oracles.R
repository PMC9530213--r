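# Independent oracles used across the suite.  These deliberately take
# different computational routes than the package implementations.

# Brute-force CCA oracle: canonical correlations as the square roots of the
# eigenvalues of Syy^-1 Syx Sxx^-1 Sxy (generalized eigenproblem route; the
# package uses QR + SVD of whitened bases).
cca_eigen_oracle <- function(Y, X) {
  Syy <- stats::cov(Y); Sxx <- stats::cov(X); Syx <- stats::cov(Y, X)
  M <- solve(Syy, Syx) %*% solve(Sxx, t(Syx))
  ev <- sort(Re(eigen(M, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(pmax(ev[seq_len(min(ncol(Y), ncol(X)))], 0))
}

# Brute-force Benjamini-Hochberg step-up: largest k with p_(k) <= k q / m
# rejects p_(1..k); adjusted values by the running-minimum definition.
bh_oracle_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, p[o] * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force partial correlation of columns i and j given all others:
# correlation of the two regression residual vectors.
partial_cor_residual_oracle <- function(ts, i, j) {
  others <- setdiff(seq_len(ncol(ts)), c(i, j))
  ri <- stats::resid(stats::lm(ts[, i] ~ ts[, others]))
  rj <- stats::resid(stats::lm(ts[, j] ~ ts[, others]))
  stats::cor(ri, rj)
}

# Small cohort configuration used where full size is not the point.
# Confound effects default to zero: these fixtures feed tests that do not
# residualize, so any confound signal would contaminate their null.
small_cohort <- function(seed, rhos = c(0.3, 0.2), n = 800, miss = 0.1,
                         mech = "MCAR", conf = 0) {
  cohort_config(n_subjects = n, canonical_rhos = rhos,
                n_brain_edges = 4, n_brain_amps = 2, n_mh_items = 6,
                n_pa_measures = 4, missing_rate = miss,
                missing_mechanism = mech, confound_effect = conf, seed = seed)
}
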