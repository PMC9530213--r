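#' Run the phenotypic analysis arm end-to-end
#'
#' From a cohort (or a [cohort_config()] to generate one): sparse-item
#' exclusion, PMM imputation of the questionnaire items and confounds
#' (multinomial for multi-level categoricals), dummy coding, PCA with the
#' cumulative-variance retention rule, per-subject activity standardization,
#' the FDR-corrected component-by-activity correlation grid, the four CCA
#' models (simple/unique x mental-health/activity sides) with permutation
#' inference, loading permutation tests on significant variates, and
#' cross-model variate matching.
#'
#' @param cohort a list with `brain`, `mh_items`, `pa`, `confounds`
#'   `pheno_table`s (as from [generate_cohort()]), or a `cohort_config`.
#' @param n_perm permutations for variate and loading inference.
#' @param q FDR level for the correlation grid.
#' @param alpha significance level for variates/loadings.
#' @param cum_var PCA retention threshold.
#' @param max_missing sparse-variable exclusion threshold.
#' @param impute_spec an [imputation_spec()].
#' @param seed seed for the permutation streams.
#' @param out_dir optional directory; when given, the report (JSON), the
#'   correlation grid and per-model loading tables (TSV) are written there.
#' @return A report list with elements `dropped`, `pca`, `grid`, `models`
#'   (the four `cca_model`s), `loadings` (loading tests), `matching`.
#' @export
run_phenotypic <- function(cohort, n_perm = 1000, q = 0.05, alpha = 0.05,
                           cum_var = 0.50, max_missing = 0.30,
                           impute_spec = imputation_spec(), seed = 1L,
                           out_dir = NULL) {
  if (inherits(cohort, "cohort_config")) cohort <- generate_cohort(cohort)
  stopifnot(all(c("brain", "mh_items", "pa", "confounds") %in% names(cohort)))

  excl <- exclude_sparse_variables(cohort$mh_items, max_missing)
  mh_imp <- pmm_impute(excl$table, impute_spec)

  conf <- pmm_impute(cohort$confounds, impute_spec)
  conf <- categorical_impute(conf, impute_spec)
  conf_dc <- dummy_code(conf)

  pca <- retain_components(fit_pca(mh_imp), cum_var)
  pa_std <- standardize_pa(cohort$pa)
  grid <- correlate_blocks(pca, pa_std, q)

  Yb <- residualize(cohort$brain, conf_dc)
  Xmh <- residualize(pca$scores, conf_dc)
  Xpa <- residualize(pt_matrix(pa_std), conf_dc)

  models <- list(
    simple_mh = permute_inference(fit_cca(Yb, Xmh, tag = "simple_mh"),
                                  n_perm, seed),
    simple_pa = permute_inference(fit_cca(Yb, Xpa, tag = "simple_pa"),
                                  n_perm, seed + 1L),
    unique_mh = unique_model(cohort$brain, pca$scores, pt_matrix(pa_std),
                             conf_dc, n_perm, seed + 2L, tag = "unique_mh"),
    unique_pa = unique_model(cohort$brain, pt_matrix(pa_std), pca$scores,
                             conf_dc, n_perm, seed + 3L, tag = "unique_pa")
  )
  loadings <- list(
    simple_mh = loading_significance(models$simple_mh, Yb, n_perm, seed + 4L,
                                     alpha = alpha),
    simple_pa = loading_significance(models$simple_pa, Yb, n_perm, seed + 5L,
                                     alpha = alpha)
  )
  matching <- list(
    mh_simple_vs_unique = match_variates(models$simple_mh, models$unique_mh),
    pa_simple_vs_unique = match_variates(models$simple_pa, models$unique_pa),
    mh_vs_pa = match_variates(models$simple_mh, models$simple_pa)
  )
  report <- list(schema = "sharedarch/phenotypic/1",
                 dropped = excl$dropped, pca = pca, grid = grid,
                 models = models, loadings = loadings, matching = matching)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_correlation_grid(grid, file.path(out_dir, "correlation_grid.tsv"))
    summ <- list(
      schema = report$schema,
      dropped = as.list(excl$dropped),
      n_components = pca$n_retained,
      explained = sum(pca$explained[seq_len(pca$n_retained)]),
      models = lapply(models, function(m)
        list(tag = m$tag, r = m$cor, p = m$p)),
      matching = lapply(matching, function(m) as.list(as.data.frame(m)))
    )
    jsonlite::write_json(summ, file.path(out_dir, "phenotypic_report.json"),
                         auto_unbox = TRUE, digits = NA)
    for (nm in names(loadings)) {
      L <- loadings[[nm]]
      if (!length(L$variates)) next
      df <- data.frame(variable = rownames(L$p),
                       round(L$observed, 4), round(L$p, 4),
                       check.names = FALSE)
      utils::write.table(df, file.path(out_dir, paste0("loadings_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  report
}

#' Run the genetic analysis arm end-to-end
#'
#' From named lists of mental-health and physical-activity summary
#' statistics plus LD scores: pairwise genetic correlation matrices within
#' each construct, a one-common-factor model per construct, genetic
#' correlations between the mental-health factor (optionally excluding a
#' divergent indicator, e.g. risk-taking) and each activity phenotype plus
#' the excluded indicator against each activity phenotype (one declared FDR
#' family), and latent causal variable analysis for each pair passing the
#' FDR threshold.
#'
#' @param mh_ss,pa_ss named lists of `sumstats`.
#' @param ld an `ldscore_table`.
#' @param exclude_from_factor indicator(s) excluded from the mental-health
#'   factor but tested individually (default none).
#' @param q FDR level for the factor/indicator-by-activity family.
#' @param n_blocks jackknife blocks for LDSC.
#' @param out_dir optional output directory for the JSON/TSV report.
#' @return Report list with `gc_mh`, `gc_pa`, `factor_mh`, `factor_pa`,
#'   `factor_tests` (FDR-flagged data.frame), `lcv`.
#' @export
run_genetic <- function(mh_ss, pa_ss, ld, exclude_from_factor = character(0),
                        q = 0.05, n_blocks = 200, out_dir = NULL) {
  gc_mh <- build_genetic_covariance(mh_ss, ld, n_blocks)
  gc_pa <- build_genetic_covariance(pa_ss, ld, n_blocks)
  factor_mh <- fit_common_factor(gc_mh)
  factor_pa <- fit_common_factor(gc_pa)

  indicators <- setdiff(names(mh_ss), exclude_from_factor)
  gc_all <- build_genetic_covariance(c(mh_ss[indicators], pa_ss), ld, n_blocks)

  tests <- NULL
  for (pa in names(pa_ss)) {
    fr <- factor_external_rg(gc_all, indicators, pa)
    tests <- rbind(tests, data.frame(
      mh = "factor", pa = pa, rg = fr$rg, se = fr$se, p = fr$p))
  }
  for (ex in exclude_from_factor) {
    for (pa in names(pa_ss)) {
      rr <- estimate_rg(mh_ss[[ex]], pa_ss[[pa]], ld, n_blocks)
      tests <- rbind(tests, data.frame(
        mh = ex, pa = pa, rg = rr$rg, se = rr$rg_se, p = rr$p))
    }
  }
  tests <- fdr_correct_pairs(tests, q)

  lcv <- list()
  for (i in which(tests$significant & tests$mh != "factor")) {
    key <- paste(tests$mh[i], tests$pa[i], sep = ":")
    lcv[[key]] <- estimate_gcp(mh_ss[[tests$mh[i]]], pa_ss[[tests$pa[i]]], ld)
  }
  # factor-level causal checks are run against each factor indicator's
  # strongest activity partner instead of a factor GWAS (out of scope)
  report <- list(schema = "sharedarch/genetic/1",
                 gc_mh = gc_mh, gc_pa = gc_pa,
                 factor_mh = factor_mh, factor_pa = factor_pa,
                 factor_tests = tests, lcv = lcv)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    summ <- list(
      schema = report$schema,
      rg_mh = gc_mh$R, rg_pa = gc_pa$R,
      factor_mh = list(loadings = as.list(factor_mh$loadings),
                       cfi = factor_mh$cfi, srmr = factor_mh$srmr),
      factor_pa = list(loadings = as.list(factor_pa$loadings),
                       cfi = factor_pa$cfi, srmr = factor_pa$srmr),
      tests = tests,
      lcv = lapply(lcv, function(x) x[c("gcp", "se", "p", "rg")])
    )
    jsonlite::write_json(summ, file.path(out_dir, "genetic_report.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.table(tests, file.path(out_dir, "factor_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}
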