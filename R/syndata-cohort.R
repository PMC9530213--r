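#' Configuration for a synthetic cohort with planted canonical structure
#'
#' Describes a generative model for four aligned participant tables — brain
#' network measures (edges + amplitudes), mental-health questionnaire items,
#' physical-activity summaries over three recording windows, and confounds —
#' in which the population canonical correlations between the brain block and
#' each behavioural block are *exactly* the requested `canonical_rhos`
#' (conditional on confounds).  The construction plants `n_latents` shared
#' standard-normal latents; loading norms are solved so that, after adding
#' independent unit-variance noise, the analytic canonical correlations equal
#' the targets (see [population_canonical_correlations()]).
#'
#' @param n_subjects number of participants.
#' @param canonical_rhos target population canonical correlations, strictly in
#'   `[0, 1)`, non-increasing.  Its length sets the number of shared latents.
#' @param n_brain_edges,n_brain_amps brain block sizes (21 edges + 7
#'   amplitudes by default, the layout analysed in the source cohort).
#' @param n_mh_items number of ordinal mental-health items.
#' @param n_pa_measures number of physical-activity measure types; each is
#'   emitted for three windows (overall/weekday/weekend), giving
#'   `3 * n_pa_measures` activity columns.
#' @param pa_within_cor within-subject correlation of a measure across the
#'   three windows (noisy replicates of one subject-level activity latent).
#' @param item_levels number of ordinal response levels per item (scalar or
#'   vector of length `n_mh_items`).
#' @param item_thresholds optional list of cut-point vectors per item on the
#'   latent scale; default: equal-probability cuts.
#' @param missing_rate per-variable missingness fraction for mental-health
#'   items and the imputable confounds, in `[0, 0.95]`.
#' @param missing_mechanism `"MCAR"` or `"MAR"` (missingness probability
#'   follows a logistic function of age).
#' @param confound_effect scale of confound effects added to the phenotype
#'   blocks (SD units per SD of confound).
#' @param seed integer seed; regenerating with the same config is
#'   bit-for-bit reproducible.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 6000,
                          canonical_rhos = c(0.25, 0.15),
                          n_brain_edges = 21, n_brain_amps = 7,
                          n_mh_items = 31, n_pa_measures = 7,
                          pa_within_cor = 0.8,
                          item_levels = 4,
                          item_thresholds = NULL,
                          missing_rate = 0.10,
                          missing_mechanism = c("MCAR", "MAR"),
                          confound_effect = 0.10,
                          seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  rhos <- as.numeric(canonical_rhos)
  if (any(rhos < 0 | rhos >= 1)) stop("canonical_rhos must lie in [0, 1)")
  if (length(rhos) > 1 && any(diff(rhos) > 1e-12)) {
    stop("canonical_rhos must be non-increasing")
  }
  if (missing_rate < 0 || missing_rate > 0.95) {
    stop("missing_rate must lie in [0, 0.95]")
  }
  K <- length(rhos)
  p_brain <- n_brain_edges + n_brain_amps
  if (K > min(p_brain, n_mh_items, n_pa_measures)) {
    stop("more canonical_rhos than the smallest block rank supports")
  }
  # PA loading needed so that the 3 noisy windows jointly carry canonical
  # correlation rho_k with the brain block: c_pa = rho * (1 + 2w) / (3w)
  w <- pa_within_cor
  c_pa <- rhos * (1 + 2 * w) / (3 * w)
  bad <- which(c_pa > 1)
  if (length(bad)) {
    stop(sprintf("canonical_rhos[%d] = %.3f infeasible for the activity block (needs loading^2 = %.3f > 1)",
                 bad[1], rhos[bad[1]], c_pa[bad[1]]))
  }
  item_levels <- rep_len(as.integer(item_levels), n_mh_items)
  if (any(item_levels < 2)) stop("item_levels must be >= 2")
  structure(list(
    n_subjects = as.integer(n_subjects), canonical_rhos = rhos,
    n_latents = K, n_brain_edges = n_brain_edges, n_brain_amps = n_brain_amps,
    n_mh_items = n_mh_items, n_pa_measures = n_pa_measures,
    pa_within_cor = w, item_levels = item_levels,
    item_thresholds = item_thresholds,
    missing_rate = missing_rate, missing_mechanism = missing_mechanism,
    confound_effect = confound_effect, seed = as.integer(seed)
  ), class = "cohort_config")
}

pa_window_names <- c("overall", "weekday", "weekend")
pa_measure_names <- c("sleep", "sedentary", "light", "moderate", "walking",
                      "activity", "met")

# Loading maps from the global latent vector z = (g, brain noise, mh noise,
# pa measure noise, pa window noise) to the observable blocks, on the
# conditional-on-confounds unit-variance scale.  Returns per-block loading
# matrices over a shared latent basis so that the analytic joint covariance
# is L %*% t(L).
cohort_loadings <- function(config) {
  K <- config$n_latents
  rhos <- config$canonical_rhos
  p <- config$n_brain_edges + config$n_brain_amps
  q <- config$n_mh_items
  m <- config$n_pa_measures
  w <- config$pa_within_cor
  nw <- length(pa_window_names)
  c_pa <- rhos * (1 + 2 * w) / (3 * w)

  dims <- c(g = K, eb = p, em = q, up = m, ep = m * nw)
  off <- stats::setNames(c(0, cumsum(dims)[-length(dims)]), names(dims))
  d <- sum(dims)
  idx <- function(block, i) off[[block]] + i

  # brain: y_k = sqrt(rho_k) g_k + sqrt(1-rho_k) e_k ; rest pure noise
  Lb <- matrix(0, p, d)
  for (j in seq_len(p)) {
    if (j <= K) {
      Lb[j, idx("g", j)] <- sqrt(rhos[j])
      Lb[j, idx("eb", j)] <- sqrt(1 - rhos[j])
    } else Lb[j, idx("eb", j)] <- 1
  }
  # mental health latent items: same diagonal structure on its own noise
  Lm <- matrix(0, q, d)
  for (j in seq_len(q)) {
    if (j <= K) {
      Lm[j, idx("g", j)] <- sqrt(rhos[j])
      Lm[j, idx("em", j)] <- sqrt(1 - rhos[j])
    } else Lm[j, idx("em", j)] <- 1
  }
  # activity: subject-level measure latent t_k, then 3 window replicates
  Lt <- matrix(0, m, d)
  for (j in seq_len(m)) {
    if (j <= K) {
      Lt[j, idx("g", j)] <- sqrt(c_pa[j])
      Lt[j, idx("up", j)] <- sqrt(1 - c_pa[j])
    } else Lt[j, idx("up", j)] <- 1
  }
  # fixed within-block rotations (seeded) spread signal across variables;
  # canonical correlations are invariant to them.  Rows of Lb/Lm/Lt are
  # orthonormal, so rotated rows keep unit variance and identity
  # within-block covariance.
  rot <- function(n, stream) {
    set.seed(config$seed * 13L + stream)
    qr.Q(qr(matrix(stats::rnorm(n * n), n)))
  }
  Lb <- rot(p, 1L) %*% Lb
  Lm <- rot(q, 2L) %*% Lm
  Lt <- rot(m, 3L) %*% Lt
  Lp <- matrix(0, m * nw, d)
  for (j in seq_len(m)) {
    for (v in seq_len(nw)) {
      row <- (j - 1) * nw + v
      Lp[row, ] <- sqrt(w) * Lt[j, ]
      Lp[row, idx("ep", row)] <- sqrt(1 - w)
    }
  }
  list(brain = Lb, mh = Lm, pa = Lp, dim = d, latent_idx = seq_len(K))
}

#' Population canonical correlations implied by a cohort configuration
#'
#' Builds the exact joint covariance of the generative model (on the latent,
#' confound-partialled scale) and returns the singular values of
#' \eqn{\Sigma_{yy}^{-1/2}\Sigma_{yx}\Sigma_{xx}^{-1/2}}, descending.  This is
#' the ground truth that CCA applied to a large generated cohort (after
#' confound residualisation) should recover; ordinal discretisation of the
#' questionnaire items attenuates the mental-health block slightly, so the
#' exact identity holds for the activity block and for the latent item scale.
#'
#' @param config a [cohort_config()].
#' @param block behavioural block to pair with the brain block: `"pa"` or
#'   `"mh"`.
#' @return Numeric vector of population canonical correlations.
#' @export
population_canonical_correlations <- function(config, block = c("pa", "mh")) {
  block <- match.arg(block)
  L <- cohort_loadings(config)
  Ly <- L$brain
  Lx <- L[[block]]
  Syy <- tcrossprod(Ly)
  Sxx <- tcrossprod(Lx)
  Syx <- Ly %*% t(Lx)
  if (min(eigen(Syy, symmetric = TRUE, only.values = TRUE)$values) < 1e-10 ||
      min(eigen(Sxx, symmetric = TRUE, only.values = TRUE)$values) < 1e-10) {
    stop("singular within-block covariance")
  }
  isq <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    e$vectors %*% (t(e$vectors) / sqrt(e$values))
  }
  sv <- svd(isq(Syy) %*% Syx %*% isq(Sxx))$d
  sort(pmin(sv, 1), decreasing = TRUE)
}

confound_names <- c("age", "sex", "site", "smoking", "drinking", "bmi",
                    "motion", "timegap")

#' Generate a synthetic cohort
#'
#' Draws the four aligned tables described by a [cohort_config()]: brain
#' network measures, ordinal mental-health items (discretised at the item
#' thresholds after confound effects are added), physical-activity summaries
#' for three windows (emitted as per-window means plus a subject-level SD
#' column per measure, so that [standardize_pa()] recovers the planted
#' structure exactly), and a confound table (age, sex, site, smoking,
#' drinking, BMI, head motion, accelerometer-to-scan time gap).
#' Missingness is applied per the configured mechanism.  The true latents and
#' generative parameters are attached as attribute `"truth"` on the returned
#' list for recovery tests.
#'
#' @param config a [cohort_config()].
#' @return A list with `pheno_table` elements `brain`, `mh_items`, `pa`,
#'   `confounds`, and attribute `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  L <- cohort_loadings(config)  # uses its own seed streams
  set.seed(config$seed)
  z <- matrix(stats::rnorm(n * L$dim), n, L$dim)
  ids <- sprintf("S%06d", seq_len(n))

  brain <- z %*% t(L$brain)
  mh <- z %*% t(L$mh)
  pa <- z %*% t(L$pa)
  g <- z[, L$latent_idx, drop = FALSE]

  # confounds -----------------------------------------------------------
  age <- stats::rnorm(n)
  sexf <- factor(sample(c("female", "male"), n, replace = TRUE))
  site <- factor(sample(paste0("site", 1:3), n, replace = TRUE))
  smoking <- factor(sample(c("never", "former", "current"), n, replace = TRUE,
                           prob = c(0.55, 0.33, 0.12)))
  drinking <- factor(sample(c("never", "occasional", "regular"), n,
                            replace = TRUE, prob = c(0.1, 0.45, 0.45)))
  bmi <- stats::rnorm(n)
  motion <- stats::rnorm(n)
  timegap <- stats::rnorm(n)
  conf_num <- cbind(age = age, sex = as.numeric(sexf) - 1.5,
                    bmi = bmi, motion = motion, timegap = timegap)

  eff <- config$confound_effect
  add_conf <- function(mat, stream) {
    set.seed(config$seed * 31L + stream)
    B <- matrix(stats::rnorm(ncol(conf_num) * ncol(mat), sd = eff),
                ncol(conf_num), ncol(mat))
    mat + conf_num %*% B
  }
  set.seed(config$seed + 7L)
  brain <- add_conf(brain, 1L)
  mh <- add_conf(mh, 2L)
  pa <- add_conf(pa, 3L)
  set.seed(config$seed + 11L)

  # name blocks ---------------------------------------------------------
  nets <- c("dDMN", "vDMN", "PCu", "aSN", "pSN", "lCEN", "rCEN")
  nets <- rep_len(nets, max(config$n_brain_amps, 1))
  edge_names <- if (config$n_brain_amps >= 2) {
    ep <- utils::combn(config$n_brain_amps, 2)
    make.unique(rep_len(
      apply(ep, 2, function(ii) paste(nets[ii], collapse = "-")),
      config$n_brain_edges))
  } else paste0("edge", seq_len(config$n_brain_edges))
  amp_names <- paste0("amp_", make.unique(nets)[seq_len(config$n_brain_amps)])
  colnames(brain) <- c(edge_names, amp_names)

  # ordinal discretisation of MH items ---------------------------------
  mh_sd <- sqrt(1 + eff^2 * ncol(conf_num))  # analytic marginal SD
  mh_ord <- mh
  thresholds <- vector("list", config$n_mh_items)
  for (j in seq_len(config$n_mh_items)) {
    Lv <- config$item_levels[j]
    cuts <- if (!is.null(config$item_thresholds)) config$item_thresholds[[j]]
            else stats::qnorm(seq_len(Lv - 1) / Lv, sd = mh_sd)
    thresholds[[j]] <- cuts
    mh_ord[, j] <- findInterval(mh[, j], cuts) + 1
  }
  colnames(mh_ord) <- sprintf("mh_item%02d", seq_len(config$n_mh_items))

  # PA: emit window means on the raw scale plus subject-level SDs so that
  # per-subject standardisation recovers the planted (standardised) values
  m <- config$n_pa_measures
  meas <- rep_len(pa_measure_names, m)
  meas <- make.unique(meas)
  pa_cols <- as.vector(t(outer(meas, pa_window_names, paste, sep = "_")))
  colnames(pa) <- pa_cols
  sds <- matrix(stats::rlnorm(n * m, meanlog = 0, sdlog = 0.3), n, m)
  colnames(sds) <- paste0(meas, "_sd")
  pa_raw <- pa
  for (j in seq_len(m)) {
    cols <- (j - 1) * 3 + 1:3
    pa_raw[, cols] <- pa[, cols] * sds[, j]
  }
  pa_out <- cbind(pa_raw, sds)

  # missingness ---------------------------------------------------------
  rate <- config$missing_rate
  miss_prob <- function() {
    if (config$missing_mechanism == "MCAR" || rate == 0) return(rep(rate, n))
    f <- function(a) mean(stats::plogis(a + age)) - rate
    a <- stats::uniroot(f, c(-20, 20))$root
    stats::plogis(a + age)
  }
  pr <- miss_prob()
  punch <- function(mat) {
    for (j in seq_len(ncol(mat))) mat[stats::runif(n) < pr, j] <- NA
    mat
  }
  if (rate > 0) mh_ord <- punch(mh_ord)

  conf_df <- data.frame(age = age, sex = sexf, site = site, smoking = smoking,
                        drinking = drinking, bmi = bmi, motion = motion,
                        timegap = timegap, row.names = ids)
  if (rate > 0) {
    for (v in c("smoking", "drinking", "bmi")) {
      conf_df[stats::runif(n) < pmin(pr / 2, 0.95), v] <- NA
    }
  }

  as_pt <- function(mat, kind) {
    df <- as.data.frame(mat); rownames(df) <- ids
    pheno_table(df, kind)
  }
  out <- list(
    brain = as_pt(brain, "continuous"),
    mh_items = as_pt(mh_ord, "ordinal"),
    pa = as_pt(pa_out, "continuous"),
    confounds = pheno_table(conf_df, c(
      age = "continuous", sex = "categorical", site = "categorical",
      smoking = "categorical", drinking = "categorical", bmi = "continuous",
      motion = "continuous", timegap = "continuous"))
  )
  attr(out, "truth") <- list(config = config, latents = g,
                             item_thresholds = thresholds,
                             mh_latent = mh, pa_standardized = pa)
  out
}
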