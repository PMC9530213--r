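# sharedarch

Joint phenotypic and genetic analysis of the shared architecture between
two behavioural constructs — prototypically mental health (MH) and physical
activity (PA) — measured alongside resting-state brain network phenotypes.
The package is aimed at population-neuroimaging / statistical-genetics
analysts who want the full two-arm workflow as tested, scriptable R
functions, with synthetic generators that plant known ground truth so every
stage has a parameter-recovery test surface.

## What it computes

**Phenotypic arm.** Questionnaire items with >30% missingness are excluded;
the rest are completed by predictive mean matching (PMM) chained equations
(20 iterations, k = 5 donors, final value averaged across iterations);
multi-level categorical confounds are imputed by multinomial logistic
regression and dummy-coded. Items are reduced by PCA, retaining the leading
components that explain >50% of variance. Activity measures are standardized
per subject by their day-to-day SD. After residualizing all blocks on the
confounds, canonical correlation analysis relates the brain block *Y* to a
behavioural block *X*:

    Y A = U  ~  V = X B,   r_k = cor(U_k, V_k)

Inference on the canonical variates uses permutations of subject
correspondence with a step-down Wilks-type statistic (closure principle);
per-variable *canonical loadings* cor(Y, U) get their own permutation test,
pooling permuted loadings across significant variates. "Unique" models add
the other behavioural block to the confounds, isolating non-shared variance,
and variates are matched across models by correlating their *U* vectors.

**Genetic arm.** From GWAS summary statistics (SNP, A1, A2, Z, N) and LD
scores: LD score regression estimates SNP heritability
(χ² regressed on N·ℓ/M) and cross-trait genetic correlation
(Z₁Z₂ regressed on √(N₁N₂)·ℓ/M, free intercept absorbing sample overlap),
with delete-one-block jackknife standard errors. A one-common-factor genomic
SEM is fitted to the genetic correlation matrix by diagonally weighted least
squares, reporting CFI/SRMR and factor–external-phenotype genetic
correlations. Latent causal variable (LCV) analysis estimates the genetic
causality proportion (GCP ∈ [−1, 1]; 0 = pure pleiotropy, ±1 = full
causality) from noise-corrected mixed third/fourth moments of normalized
effect sizes.

**Synthetic generators.** `generate_cohort()` plants an exact set of
population canonical correlations between blocks (via shared latents with
solved loading norms; `population_canonical_correlations()` is the
closed-form oracle), ordinal item discretisation, confound effects,
MCAR/MAR missingness and three correlated activity windows.
`generate_sumstats()` draws Z-score pairs obeying the LDSC moment model with
configurable h², r_g, sample overlap and LCV causal architecture;
`generate_sumstats_set()` / `generate_sumstats_two_sets()` build one- and
two-factor multi-trait panels.

## Worked example

```r
library(sharedarch)

cfg <- cohort_config(n_subjects = 2000, canonical_rhos = c(0.25, 0.15), seed = 42)
cohort <- generate_cohort(cfg)

conf  <- dummy_code(categorical_impute(pmm_impute(cohort$confounds),
                                       imputation_spec(seed = 1)))
items <- pmm_impute(exclude_sparse_variables(cohort$mh_items)$table,
                    imputation_spec(seed = 1))
retain_components(fit_pca(items))
#> <pca_result> 14 components over 31 variables; 14 retained (51.8% variance)

Y <- residualize(cohort$brain, conf)
X <- residualize(pt_matrix(standardize_pa(cohort$pa)), conf)
permute_inference(fit_cca(Y, X), n_perm = 500, seed = 7)
#> <cca_model> 21 variate pairs, n = 2000
#>   r: 0.296 0.237 0.200 0.166 0.157 ...
#>   p: 0.002 0.255 0.930 0.998 1.000
```

The first canonical pair (estimated r₁ = 0.30 against a planted 0.25 plus
overfitting bias at n = 2000) is significant; the second planted pair
(ρ₂ = 0.15) is below detection power at this sample size — at n = 6000 the
suite's recovery test finds exactly two significant variates in ≥90% of
seeds.

```r
d <- generate_sumstats(sumstats_config(m_snps = 50000, n1 = 2e5, n2 = 1e5,
       h2_1 = 0.10, h2_2 = 0.21, rho_g = 0.12 * sqrt(0.10 * 0.21), seed = 42))
rg <- estimate_rg(d$ss1, d$ss2, d$ld)
#> rg = 0.134 (SE 0.010), p = 9.6e-40, cross-intercept = -0.062
estimate_gcp(d$ss1, d$ss2, d$ld)
#> <lcv_result> GCP = -0.299 (SE 2.326), p = 0.696, rg = 0.134
```

The genetic correlation planted at 0.12 is recovered within two standard
errors; with no causal architecture planted the GCP test correctly finds no
evidence of causality.

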