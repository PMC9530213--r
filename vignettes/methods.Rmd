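---
title: "Methods: models, parameters and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models implemented by `sharedarch`,
the tunable parameters that matter, the design choices made where the design
was genuinely open, and what a green test does and does not establish. No
empirical number is claimed here that the test suite does not itself
compute.

## 1. The synthetic cohort: a stated world

`generate_cohort()` draws a cohort in which the *population* canonical
correlations between the brain block and each behavioural block equal the
requested `canonical_rhos` exactly, conditional on confounds. The
construction plants `K = length(canonical_rhos)` shared standard-normal
latents `g`. On the unit-variance conditional scale:

* brain variable *k* (k ≤ K) is `sqrt(rho_k) g_k + sqrt(1 - rho_k) e`,
  remaining brain variables are pure noise; an orthogonal rotation (fixed by
  the seed) spreads signal across all 28 columns without changing the
  canonical spectrum;
* mental-health latent items follow the same diagonal construction, so the
  brain–MH canonical correlations are `rho` exactly *on the latent scale*;
* each activity measure is a subject-level latent replicated into three
  windows with within-subject correlation `pa_within_cor` (default 0.8,
  chosen to mimic the strong overall/weekday/weekend redundancy of
  accelerometer summaries). The measure loading is inflated by
  `(1 + 2w) / (3w)` so that the three noisy windows *jointly* carry
  canonical correlation `rho_k` — this is the "solve loading norms given
  noise variances" rule, and it is why
  `population_canonical_correlations()` returns the planted values to
  1e-10. Targets above `3w / (1 + 2w)` (≈ 0.923 at w = 0.8) are infeasible
  and rejected with the offending index named.

Confound effects (age, sex, site, smoking, drinking, BMI, head motion,
accelerometer-to-scan time gap; coefficient scale `confound_effect`, default
0.1 SD per SD) are added *on top* of this structure. Because confounds are
independent of the latents, the covariance conditional on confounds — what
CCA sees after residualization — is exactly the clean construction. The
analytic oracle is therefore exact for the activity block and for the
latent item scale; ordinal discretisation of the items (default 4
equal-probability levels; level counts are configurable since item-level
response distributions are not published) attenuates the realized MH-side
correlations slightly. Recovery tests use the activity block for this
reason.

Activity tables are emitted as window means multiplied by a lognormal
subject-level SD, plus the SD column; `standardize_pa()` divides the means
by the SD, recovering the planted standardized values exactly. Missingness
is MCAR at `missing_rate` or MAR with probability logistic in age (the
intercept solved so the marginal rate matches).

What the generator does **not** emulate: raw fMRI timeseries or
accelerometer traces, genotypes, item-level dependencies between
questionnaire branches, non-Gaussian phenotype marginals, and confound–
latent correlation. A green recovery test establishes that the estimators
recover a planted linear-Gaussian truth, not that they are robust to those
real-data features.

## 2. Imputation

`pmm_impute()` implements chained-equation predictive mean matching:
per incomplete variable and iteration, a linear regression on all other
(currently completed) variables is fitted on the originally observed rows;
coefficients are drawn from the approximate posterior (normal around the
estimate, residual variance from a scaled chi-squared draw); the `k = 5`
nearest observed predictions donate, one chosen at random ("three or five"
donors are conventional; five is the common default). Visit order is
ascending missingness; the initial fill draws from each variable's observed
values. The final value averages all 20 iterations — deliberately including
every iteration, with no burn-in discard, and deliberately applied to
ordinal items too, so averaged items may be non-integer and PCA consumes
them as continuous. Deterministic mode (`draw_coefficients = FALSE`,
`n_donors = 1`) exists solely so tests can match a brute-force
nearest-prediction oracle exactly.

Categorical variables use multinomial logistic regression (softmax maximum
likelihood with a 1e-6 ridge; `nnet` is not assumed available), drawing the
imputed level from predicted class probabilities per iteration; the final
level is the modal draw, ties resolved by the fixed level order and logged.
Levels unseen in training rows get zero probability.

## 3. PCA, retention, correlations

PCA operates on z-scored items (correlation-matrix convention — items sit
on heterogeneous response scales; the alternative covariance convention
would let wide-scaled items dominate). Component signs are fixed so each
loading column's largest-magnitude entry is positive. Retention keeps the
smallest leading set whose cumulative explained variance *strictly* exceeds
`cum_var = 0.50`. The component-by-activity correlation grid uses Pearson
correlations with two-sided t p-values and Benjamini–Hochberg adjustment
over the whole grid as a single declared family (7 × 21 = 147 tests in the
reference layout); zero-variance pairs are reported `NA` and excluded from
the family with a log entry.

## 4. CCA and permutation inference

`fit_cca()` orthonormalizes each centered block by QR and takes the SVD of
the cross-product of the bases — numerically the whitened cross-covariance.
The SVD is a *full* SVD: the rotated bases retain all `p` and `q`
dimensions, which the step-down permutation scheme needs (testing variate
`k` drops the first `k - 1` columns of both rotated bases — exactly the
estimated canonical directions — and takes the singular values of the
remaining cross-product block).

Permutation inference shuffles subject correspondence; the statistic for
variate `k` is `-sum(log(1 - r_i^2))` over `i >= k` computed on the
residual blocks (closure principle), one permutation stream reused across
`k`. P-values use the add-one rule `(count + 1) / (n_perm + 1)` — a
deliberate deviation from a plain `/n_perm` divisor to avoid impossible
zero p-values (difference ≤ 0.001 at 1000 permutations) — and are forced
monotone by cumulative maximum. Rows are exchangeable only approximately
after confound residualization; `huh_jhun_reduce()` offers the
semi-orthogonal reduction for exact exchangeability (default off; the
calibration criterion shows the default's type-I error is within
[0.03, 0.07] at n = 500).

The loading test records, per permutation, each brain variable's loading
magnitude on every significant variate and pools these across variates into
one null per variable — the "corrected for the number of significant
variates" rule implemented literally as pooling, not Bonferroni. Magnitudes
are compared (two-sided on |loading|) because canonical signs are
arbitrary; signed nulls are retained in the result for audit. Unique models
append the other behavioural block to the confounds and residualize *both*
sides by default (symmetric treatment; `partial = "y-only"` gives the
narrower variant). Variate matching is greedy on |cor(U_a, U_b)| with ties
broken by variate index.

## 5. LD score regression

Heritability: weighted regression of χ² on `N l / M` with free intercept;
genetic covariance: `Z1 Z2` on `sqrt(N1 N2) l / M`, the intercept absorbing
sample overlap. Weights follow the canonical two-step scheme — first pass
`1/l`, second pass inverse squared expected outcome evaluated at the
first-pass fit (for the cross regression, `1/(l (v1 v2 + c^2))`, the
variance of a product of correlated normals). This makes a trait regressed
on itself produce rg = 1 *exactly*, since the cross regression's weights
become proportional to the χ² regression's. Standard errors come from a
delete-one jackknife over 200 contiguous SNP blocks (the usual
resolution/variance trade-off); the rg ratio is jackknifed jointly with its
component slopes. `build_genetic_covariance()` assembles S (h² diagonal,
genetic covariances off it) with V the joint jackknife covariance of S's
unique elements; the covariance of the correlation-metric elements is kept
separately (`V_rg`) for the SEM weights. No χ² capping is applied by
default — synthetic data lack the outliers that motivate it.

## 6. Genomic SEM

The one-factor model is fitted to the genetic correlation matrix by
diagonally weighted least squares, weights `1/Var(r_ij)` from the jackknife
(unit weights for exact population input). Loadings are bounded to
[−1, 1]; a boundary solution is flagged as a Heywood case with residual
variance bounded at 0. Optimization runs from five deterministic starts
(constant grids, sign patterns from the first correlation row) and keeps
the best discrepancy — no randomness. The model χ² is the weighted residual
quadratic form scaled by `df / tr(U V)` (sandwich mean-correction against
the full sampling covariance); CFI is computed against the independence
model and reported clamped to [0, 1] with the raw value retained. With no
sampling covariance (exact population matrix) the χ² scaling is undefined,
so CFI degrades gracefully to the discrepancy ratio
`1 - F_model / F_independence` — 1 for exact fit, visibly below 1 for
structural misfit, which is the regime the misfit criterion checks. SRMR
averages squared residuals over the lower triangle including the
(identically zero, in correlation metric) diagonal — stated to remove
ambiguity. The factor–external model adds one freely correlated phenotype
(implied cross-correlations `lambda_i * phi`); the SE of `phi` is the
sandwich `(Δ'WΔ)^{-1} Δ'W V W Δ (Δ'WΔ)^{-1}` evaluated at the solution.
The factor is oriented so the first indicator loads positively.

## 7. Latent causal variable analysis

With per-SNP standardized effects `alpha_i = q_i pi + delta_i` and `pi`
heavy-tailed with excess kurtosis κ, the noise-corrected mixed moments are
`m31 = E[x1^3 x2] - 3 rho (1 + v1) - 3 c12 E[x1^2] = kappa q1^3 q2` and
symmetrically `m13`; the loading ratio gives
`GCP = log(q2^2 / q1^2) / log(rho^2)`, clamped to [−1, 1], positive when
trait 1 is partially causal for trait 2. Normalization uses the LDSC
heritabilities *and intercepts* (the intercept carries the actual noise
level, which also makes the estimator exactly invariant to rescaling either
trait's Z-scores). SNPs are weighted `1/l` to de-emphasize high-LD regions.

Two numerical choices matter:

* **The causality test statistic is the moment difference `m31 - m13`,**
  not the GCP log-ratio. The difference is nearly linear in the blockwise
  sums, so its 100-block jackknife is well calibrated; the log-ratio is too
  nonlinear for delete-one variance estimation (its jackknife SE
  underestimated the Monte-Carlo spread by ~20% in development, inflating
  null rejection). The GCP point estimate and its (approximate) jackknife
  SE are still reported.
* **All LDSC normalization estimates are propagated through the
  jackknife.** The moments are expanded into raw blockwise sums independent
  of any estimate, and each delete-block statistic is recomputed with that
  block's own heritabilities, intercepts and rg. Holding them fixed leaves
  out a variance component of the same order as the moment noise.

100 blocks (vs LDSC's 200) because fourth moments are noisier. GCP is
unidentified under exactly normal effects (κ = 0); the generator's
`tail_prob = 0.1` spike mixture (κ = 27) reflects the concentrated
architectures the estimator assumes. Pairs whose |rg| is below twice its SE
are flagged underpowered with p = 1 rather than risking a moment ratio with
no signal.

## 8. Degenerate inputs and tie-breaks (summary)

Constant timeseries → amplitude 0. Singular covariance with ridge 0 →
error advising ridge > 0 (the ridge acts on the correlation matrix, making
it scale-free). All-variables-excluded, sub-200-SNP merges, non-positive
heritability, fewer complete donors than `k`, more variables than subjects →
explicit errors. Negative ĥ² is returned flagged, never clamped.
Categorical imputation ties → fixed level order, logged. Canonical
correlation ties in variate matching → variate index.

## 9. Known limitations

The MH-side canonical truth is exact only on the latent scale; ordinal
attenuation is a property of the stated world, not a bug, and is why the
headline recovery criterion uses the activity block. Jackknife SEs
(LDSC ~10%, factor-external ~25% under-dispersion in development
measurements at the tested scales) are adequate for 2-SE coverage criteria
but not exact. The DWLS SEM has no multi-factor search; the LCV moment
estimator assumes a single latent mediator and heavy-tailed effects. The
permutation schemes assume exchangeable rows after residualization unless
the Huh–Jhun reduction is enabled.
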