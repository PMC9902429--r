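#' Fit a case/control serum study
#'
#' Wraps [fit_abundance_model()] with the two-group design used for the
#' synthetic serum studies: standardized log abundances regressed on group
#' (case vs control), ordinary least squares with empirical-Bayes variance
#' moderation, single `case_vs_control` contrast.
#'
#' @param study a list from [generate_serum_study()], or a list with
#'   `abundance` (raw matrix) and `samples` (`sample_id`, `group`).
#' @return An `abundance_fit`.
#' @export
fit_serum_model <- function(study) {
  z <- standardize(log_transform(study$abundance))
  cm <- matrix(c(0, 1), 2, 1,
               dimnames = list(c("(Intercept)", "groupcase"), "case_vs_control"))
  fit_abundance_model(z, study$samples, block = NULL, rho = 0,
                      formula = ~ group, contrast_matrix = cm)
}

#' Run the full regional differential-abundance pipeline
#'
#' Executes the stages in their canonical order on a raw study: natural-log
#' transform, per-(region, batch) median normalization, missingness/variance
#' filtering, mechanism classification, mechanism-aware imputation, quantile
#' normalization, PCA QC, standardization, the moderated GLS fit, the three
#' region contrasts, pathway rotation enrichment, pathway PC differential
#' testing and spatial pattern clusters.
#'
#' @param abundance raw `abundance_matrix`.
#' @param samples sample table.
#' @param annotation pathway annotation.
#' @param config a [run_config()].
#' @return List with `qc`, `report` (missingness mechanisms), `dropped`,
#'   `imputed` (final matrix), `fit`, `results` (contrast results),
#'   `covariates`, `enrichment` (per-contrast list), `pathway_scores`,
#'   `pathway_results`, `patterns`, `pattern_summary`.
#' @export
run_region_pipeline <- function(abundance, samples, annotation,
                                config = run_config()) {
  logm <- log_transform(abundance)
  norm <- median_normalize(logm, samples)
  filt <- filter_metabolites(norm, config$missingness_cutoff)
  report <- missingness_report(filt$matrix, config)
  imputed <- impute_abundance(filt$matrix, report, seed = config$seed)
  qn <- quantile_normalize(imputed)
  qc <- pca_qc(qn, samples, config$control_metabolite_ids)
  z <- standardize(qn)
  fit <- fit_abundance_model(z, samples)
  results <- test_contrasts(fit, config$fdr_cutoff)
  covs <- covariate_effects(fit, config$fdr_cutoff)
  sets <- split(annotation$metabolite_id, annotation$family)
  enrichment <- lapply(colnames(fit$contrast_matrix), function(ct)
    classify_direction(
      rotation_set_test(fit, sets, contrast = ct,
                        n_rotations = config$n_rotations,
                        min_subset_size = config$min_subset_size,
                        seed = config$seed),
      config$fdr_cutoff))
  names(enrichment) <- colnames(fit$contrast_matrix)
  ps <- pathway_pc_scores(z, annotation)
  pres <- pathway_pc_differential(ps, samples, rho = fit$correlation,
                                  fdr_cutoff = config$fdr_cutoff)
  pat <- assign_patterns(results, config$fdr_cutoff)
  list(qc = qc, report = report, dropped = filt$dropped, imputed = qn,
       fit = fit, results = results, covariates = covs,
       enrichment = enrichment, pathway_scores = ps, pathway_results = pres,
       patterns = pat,
       pattern_summary = cluster_summary(pat, annotation))
}
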