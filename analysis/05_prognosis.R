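# Prognostic comparison: logistic metabolomic mortality score (8-metabolite
# panel at 0h and 24h, leave-one-out cross-validated) against the
# SOFA-based score; ROC curves, diagnostic indices at the Youden point and
# the paired bootstrap AUC difference.

source("analysis/_common.R")

cohort <- read_cohort(file.path(DATA_DIR, "cohort.csv"))
cohort0 <- cohort[cohort$timepoint == "0h", ]
panel0 <- read.csv(file.path(RESULTS_DIR, "panel_0h.csv"),
                   check.names = FALSE)
panel24 <- read.csv(file.path(RESULTS_DIR, "panel_24h.csv"),
                    check.names = FALSE)
y <- as.numeric(cohort0$outcome == "non-survivor")
cfg <- default_config()$prognosis

met <- cv_metabolomic_score(panel0, panel24, y, mode = cfg$predictors,
                            ridge = cfg$ridge)
sofa <- cv_sofa_score(cohort0$SOFA_0h, cohort0$SOFA_24h, y)

scores <- data.frame(subject_id = cohort0$subject_id, outcome = y,
                     metabolomic = met, sofa = sofa)
write_table(scores, "prognostic_scores.csv")

roc_tab <- do.call(rbind, lapply(c(metabolomic = "metabolomic",
                                   sofa = "sofa"), function(sc) {
  r <- roc_curve(scores[[sc]], y, cfg$conf_level, cfg$n_boot, seed = SEED)
  data.frame(score = sc, threshold = r$thresholds,
             sensitivity = r$sensitivity, specificity = r$specificity,
             auc = r$auc, ci_lower = r$ci[["lower"]],
             ci_upper = r$ci[["upper"]])
}))
write_table(roc_tab, "roc_curves.csv")

idx <- do.call(rbind, lapply(c("metabolomic", "sofa"), function(sc) {
  d <- diagnostic_indices(scores[[sc]], y, conf_level = cfg$conf_level)
  cbind(score = sc, as.data.frame(d), threshold = attr(d, "threshold"))
}))
write_table(idx, "diagnostic_indices.csv")

cmp <- compare_scores(met, sofa, y, n_boot = cfg$n_boot,
                      conf_level = cfg$conf_level, seed = SEED)
perm <- permutation_test_auc(score_predictors(panel0, panel24,
                                              cfg$predictors),
                             y, ridge = cfg$ridge, seed = SEED)
write_table(data.frame(auc_metabolomic = cmp$auc_a, auc_sofa = cmp$auc_b,
                       delta = cmp$delta, ci_lower = cmp$ci[["lower"]],
                       ci_upper = cmp$ci[["upper"]],
                       delta_p = cmp$p_value,
                       metabolomic_permutation_p = perm$p_value),
            "score_comparison.csv")
cat(sprintf("metabolomic AUC %.3f vs SOFA %.3f (delta %.3f, p=%.4f)\n",
            cmp$auc_a, cmp$auc_b, cmp$delta, cmp$p_value))
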