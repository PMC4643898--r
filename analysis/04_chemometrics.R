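# Multivariate modelling per collection: PCA outlier screen, PLS-DA with
# the component count chosen by leave-one-out RMSECV, cross-validation
# (Q2_press, Q2_corr, RMSECV), ROC of the out-of-fold predictions, and the
# permutation overfit test. Emits scores/loadings tables and a validation
# summary.

source("analysis/_common.R")

cohort <- read_cohort(file.path(DATA_DIR, "cohort.csv"))

validation <- list()
for (tp in c("0h", "24h")) {
  mat <- read.csv(file.path(RESULTS_DIR,
                            sprintf("binned_matrix_%s.csv", tp)),
                  check.names = FALSE)
  ids <- mat$sample_id
  X <- as.matrix(mat[, -1])
  y <- cohort$outcome[match(ids, cohort$sample_id)] == "non-survivor"

  outliers <- pca_screen(X)
  write_table(data.frame(sample_id = ids, outliers),
              sprintf("pca_outliers_%s.csv", tp))
  keep <- !outliers$flag
  X <- X[keep, , drop = FALSE]; y <- as.numeric(y[keep]); ids <- ids[keep]

  sel <- select_components(X, y)
  cv <- loo_cv(X, y, sel$A, seed = SEED)
  model <- plsda_fit(X, y, sel$A)
  roc <- roc_curve(cv$predictions, y, seed = SEED)
  perm <- permutation_test(X, y, sel$A, seed = SEED)

  write_table(data.frame(sample_id = ids, outcome = y, model$scores,
                         cv_prediction = cv$predictions,
                         check.names = FALSE),
              sprintf("plsda_scores_%s.csv", tp))
  write_table(rank_loadings(model, colnames(X)),
              sprintf("plsda_loadings_%s.csv", tp))

  validation[[tp]] <- data.frame(
    timepoint = tp, n = length(y), components = sel$A,
    R2Y = model$R2Y, Q2_press = cv$Q2_press, Q2_corr = cv$Q2_corr,
    RMSECV = cv$RMSECV, cv_auc = roc$auc,
    permutation_p = perm$p_value, outliers_excluded = sum(!keep))
  cat(sprintf("%s: A=%d R2Y=%.3f Q2=%.3f AUC=%.3f perm p=%.4f\n",
              tp, sel$A, model$R2Y, cv$Q2_press, roc$auc, perm$p_value))
}
write_table(do.call(rbind, validation), "plsda_validation.csv")
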