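# End-to-end convenience wrappers tying the stages together the way the
# analysis scripts and reports use them.

#' Fit and validate one timepoint's discriminant model
#'
#' Runs the fixed preprocessing order (TSP referencing, bucketing, optional
#' region exclusion, aliphatic normalization) on one timepoint's spectra,
#' screens PCA outliers, selects the PLS component count by leave-one-out
#' RMSECV, fits the PLS-DA model, cross-validates it (Q2_press, Q2_corr,
#' RMSECV), evaluates the ROC of the out-of-fold predictions, and runs the
#' permutation overfit test.
#'
#' @param spectra Named list of `spectrum` objects for one timepoint.
#' @param outcome 0/1 vector aligned with `spectra` (1 = non-survivor).
#' @param config Pipeline configuration, see [default_config()].
#' @param drop_outliers Remove flagged samples before modelling (the source
#'   workflow excluded its PCA outliers).
#' @param seed Seed for cross-validation splits, permutations and the ROC
#'   bootstrap.
#' @return List: `matrix` (normalized `binned_matrix`), `outliers`,
#'   `A`, `model`, `cv` (`cv_result`), `roc` (`roc_result` of the
#'   out-of-fold predictions), `permutation` (`permutation_result`),
#'   `outcome` (after any outlier removal).
#' @export
fit_timepoint_model <- function(spectra, outcome, config = default_config(),
                                drop_outliers = TRUE, seed = 1) {
  stopifnot(length(spectra) == length(outcome))
  b <- config$binning
  m <- bin_cohort(spectra, b$low_ppm, b$high_ppm, b$width_ppm)
  if (!is.null(config$exclusion$water_region)) {
    m <- exclude_regions(m, list(config$exclusion$water_region))
  }
  m <- normalize_aliphatic(m, config$normalization$region_low_ppm,
                           config$normalization$region_high_ppm)
  outliers <- pca_screen(m$values, config$outliers$cum_var,
                         config$outliers$alpha)
  y <- as.numeric(outcome)
  if (drop_outliers && any(outliers$flag)) {
    keep <- !outliers$flag
    m$values <- m$values[keep, , drop = FALSE]
    m$sample_ids <- m$sample_ids[keep]
    y <- y[keep]
    log_msg("INFO", "excluded ", sum(!keep), " PCA outlier(s)")
  }
  sel <- select_components(m$values, y, config$pls$max_components)
  cv <- loo_cv(m$values, y, sel$A, cv_repeats = config$pls$cv_repeats,
               cv_folds = config$pls$cv_folds, seed = seed)
  model <- plsda_fit(m$values, y, sel$A)
  roc <- roc_curve(cv$predictions, y, seed = seed)
  perm <- permutation_test(m$values, y, sel$A,
                           statistic = config$permutation$statistic,
                           n_perm = config$permutation$n_perm, seed = seed)
  list(matrix = m, outliers = outliers, A = sel$A, model = model, cv = cv,
       roc = roc, permutation = perm, outcome = y)
}

#' Metabolomic vs SOFA prognosis comparison on a cohort
#'
#' Quantifies the 8-metabolite panel at both collections, computes
#' cross-validated metabolomic and SOFA mortality scores, and compares their
#' ROC curves with paired bootstrap. All score evaluation is out-of-fold.
#'
#' @param cohort A `cohort_table` (two samples per subject).
#' @param spectra Named list of `spectrum` objects covering every sample.
#' @param config Pipeline configuration.
#' @param seed Seed (bootstrap, permutations).
#' @param n_perm Permutations for the score AUC test (0 to skip).
#' @return List: `panel0h`, `panel24h`, `metabolomic` (probabilities, roc,
#'   indices), `sofa` (likewise), `comparison`, `permutation`, `outcome`.
#' @export
run_prognosis <- function(cohort, spectra, config = default_config(),
                          seed = 1, n_perm = 200) {
  cohort0 <- cohort[cohort$timepoint == "0h", ]
  cohort24 <- cohort[cohort$timepoint == "24h", ]
  common <- intersect(cohort0$subject_id, cohort24$subject_id)
  dropped <- setdiff(unique(cohort$subject_id), common)
  if (length(dropped)) {
    log_msg("WARN", length(dropped),
            " subject(s) lack one timepoint and are excluded: ",
            paste(dropped, collapse = ", "))
  }
  cohort0 <- cohort0[match(common, cohort0$subject_id), ]
  cohort24 <- cohort24[match(common, cohort24$subject_id), ]

  ref <- function(ids) lapply(spectra[ids], reference_to_tsp)
  panel0 <- cohort_panel(ref(cohort0$sample_id))
  panel24 <- cohort_panel(ref(cohort24$sample_id))
  y <- as.numeric(cohort0$outcome == "non-survivor")
  ridge <- config$prognosis$ridge
  mode <- config$prognosis$predictors

  met_probs <- cv_metabolomic_score(panel0, panel24, y, mode = mode,
                                    ridge = ridge)
  sofa_probs <- cv_sofa_score(cohort0$SOFA_0h, cohort0$SOFA_24h, y)

  met_roc <- roc_curve(met_probs, y, config$prognosis$conf_level,
                       config$prognosis$n_boot, seed)
  sofa_roc <- roc_curve(sofa_probs, y, config$prognosis$conf_level,
                        config$prognosis$n_boot, seed)
  comparison <- compare_scores(met_probs, sofa_probs, y,
                               n_boot = config$prognosis$n_boot, seed = seed)
  perm <- if (n_perm > 0) {
    permutation_test_auc(score_predictors(panel0, panel24, mode), y,
                         ridge = ridge, n_perm = n_perm, seed = seed)
  } else NULL
  list(panel0h = panel0, panel24h = panel24,
       metabolomic = list(probabilities = met_probs, roc = met_roc,
                          indices = diagnostic_indices(met_probs, y)),
       sofa = list(probabilities = sofa_probs, roc = sofa_roc,
                   indices = diagnostic_indices(sofa_probs, y)),
       comparison = comparison, permutation = perm, outcome = y,
       subjects = common)
}
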