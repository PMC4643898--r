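# Prognosis: logistic-regression metabolomic mortality score, ROC analysis
# with diagnostic indices, and comparison against the SOFA-based score.

#' Fit a logistic regression model
#'
#' Maximum likelihood via iteratively reweighted least squares
#' (`stats::glm`); with `ridge > 0`, a fixed-penalty ridge-regularised fit
#' (`glmnet`, alpha = 0) used to stabilise models with many predictors and
#' few events. Predictors are standardised internally; coefficients are
#' reported on the original scale.
#'
#' @param features Numeric matrix or data.frame of predictors.
#' @param outcome 0/1 vector (1 = event, e.g. 30-day death).
#' @param ridge Ridge penalty lambda; 0 (default) for the unpenalised fit.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return A `logistic_model`: `coefficients` (named, intercept first),
#'   `converged`, `n_iterations`, `separation` flag, `ridge`.
#' @export
logistic_fit <- function(features, outcome, ridge = 0, max_iter = 100,
                         tol = 1e-9) {
  X <- as.matrix(features)
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) {
    stop_sepsimet("sepsimet_invalid_argument", "outcome must be coded {0, 1}")
  }
  if (length(unique(y)) < 2) {
    stop_sepsimet("sepsimet_invalid_argument",
                  "both outcome classes must be present")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  separation <- FALSE
  if (ridge > 0) {
    # glmnet requires >= 2 columns; pad with a zero column and drop its
    # (necessarily zero) coefficient afterwards
    Xg <- if (ncol(X) < 2) cbind(X, `.pad` = 0) else X
    fit <- withCallingHandlers(
      glmnet::glmnet(Xg, y, family = "binomial", alpha = 0,
                     lambda = ridge, standardize = TRUE,
                     maxit = max_iter * 1000, thresh = tol),
      warning = function(w) {
        # few events per class is the norm in this domain (e.g. 12 deaths
        # among 60); the penalty is there precisely for that, so demote
        # glmnet's small-class caution to a log line
        if (grepl("fewer than 8", conditionMessage(w))) {
          log_msg("DEBUG", "glmnet: ", conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      })
    coefs <- stats::setNames(as.numeric(stats::coef(fit, s = ridge)),
                             c("(Intercept)", colnames(Xg)))
    coefs <- coefs[c("(Intercept)", colnames(X))]
    model <- list(coefficients = coefs, converged = TRUE,
                  n_iterations = fit$npasses, separation = FALSE,
                  ridge = ridge)
  } else {
    wh <- withCallingHandlers(
      fit <- stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                            family = stats::binomial(),
                            control = stats::glm.control(
                              maxit = max_iter, epsilon = tol)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) separation <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (separation || !fit$converged) {
      stop_sepsimet("sepsimet_nonconvergence",
                    paste0("logistic fit did not converge",
                           if (separation) " (complete separation detected;",
                           if (separation) " consider a small ridge penalty)"))
    }
    model <- list(coefficients = fit$coefficients, converged = fit$converged,
                  n_iterations = fit$iter, separation = separation,
                  ridge = 0)
  }
  structure(model, class = "logistic_model")
}

#' Predicted event probabilities from a logistic model
#'
#' @param object A `logistic_model`.
#' @param newdata Predictor matrix/data.frame with the model's columns.
#' @param ... Unused.
#' @return Probabilities in (0, 1).
#' @export
predict.logistic_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  eta <- object$coefficients[1] +
    drop(X %*% object$coefficients[-1])
  stats::plogis(eta)
}

#' Subject-level predictor matrix from the 0h and 24h panels
#'
#' `"both-timepoints"` uses every panel level at 0h and at 24h (16 columns
#' for the 8-metabolite panel); `"baseline-delta"` uses the 0h levels plus
#' the 24h minus 0h deltas.
#'
#' @param panel0h,panel24h [cohort_panel()] data.frames aligned by row.
#' @param mode Predictor construction.
#' @return Numeric matrix, one row per subject.
#' @export
score_predictors <- function(panel0h, panel24h,
                             mode = c("both-timepoints", "baseline-delta")) {
  mode <- match.arg(mode)
  meta <- setdiff(names(panel0h), "sample_id")
  if (!identical(meta, setdiff(names(panel24h), "sample_id"))) {
    stop_sepsimet("sepsimet_schema_error",
                  "0h and 24h panels list different metabolites")
  }
  m0 <- as.matrix(panel0h[, meta, drop = FALSE])
  m24 <- as.matrix(panel24h[, meta, drop = FALSE])
  if (nrow(m0) != nrow(m24)) {
    stop_sepsimet("sepsimet_schema_error",
                  "0h and 24h panels have different sample counts")
  }
  if (mode == "both-timepoints") {
    out <- cbind(m0, m24)
    colnames(out) <- c(paste0(meta, "_0h"), paste0(meta, "_24h"))
  } else {
    out <- cbind(m0, m24 - m0)
    colnames(out) <- c(paste0(meta, "_0h"), paste0(meta, "_delta"))
  }
  out
}

#' Metabolomic mortality score for a cohort
#'
#' Builds the subject-level predictor matrix from the 8-metabolite panels at
#' both urine collections ("evolution": 0h and 24h levels as 16 predictors,
#' or baseline + delta), fits the logistic model, and returns per-subject
#' probabilities of 30-day death. Subjects missing either timepoint are
#' excluded with a logged warning.
#'
#' @param panel0h,panel24h [cohort_panel()] data.frames, one row per subject,
#'   aligned by row (same subject order).
#' @param outcome 0/1 vector (1 = non-survivor), aligned with the panels.
#' @param mode Predictor construction, see Details.
#' @param ridge Ridge penalty for the fit (0 = unpenalised).
#' @return List: `probabilities`, `model` (`logistic_model`), `predictors`.
#' @export
metabolomic_score <- function(panel0h, panel24h, outcome,
                              mode = c("both-timepoints", "baseline-delta"),
                              ridge = 0) {
  X <- score_predictors(panel0h, panel24h, mode)
  model <- logistic_fit(X, outcome, ridge = ridge)
  list(probabilities = predict(model, X), model = model, predictors = X)
}

#' Cross-validated metabolomic score
#'
#' Leave-one-subject-out: the logistic model is refitted without each
#' subject and that subject's probability is predicted out-of-fold, so the
#' score's ROC evaluation carries no in-sample optimism. With 16 predictors
#' and few events the fold models use a small fixed ridge penalty.
#'
#' @inheritParams metabolomic_score
#' @param ridge Ridge penalty used inside the folds (default 0.1).
#' @return Out-of-fold probability per subject.
#' @export
cv_metabolomic_score <- function(panel0h, panel24h, outcome,
                                 mode = c("both-timepoints", "baseline-delta"),
                                 ridge = 0.1) {
  X <- score_predictors(panel0h, panel24h, mode)
  cv_logistic_probs(X, as.numeric(outcome), ridge)
}

cv_logistic_probs <- function(X, y, ridge) {
  n <- nrow(X)
  probs <- numeric(n)
  for (i in seq_len(n)) {
    y_tr <- y[-i]
    if (length(unique(y_tr)) < 2) {
      probs[i] <- mean(y_tr)
      next
    }
    fit <- logistic_fit(X[-i, , drop = FALSE], y_tr, ridge = ridge)
    probs[i] <- predict(fit, X[i, , drop = FALSE])
  }
  probs
}

#' Permutation test for the cross-validated score AUC
#'
#' Permutes outcome labels, recomputes the out-of-fold score and its AUC
#' each time, and reports `p = (1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param X Predictor matrix (subjects x predictors).
#' @param outcome 0/1 vector.
#' @param ridge Ridge penalty inside folds.
#' @param n_perm Number of permutations.
#' @param seed Seed.
#' @return A `permutation_result` for the AUC.
#' @export
permutation_test_auc <- function(X, outcome, ridge = 0.1, n_perm = 200,
                                 seed = 1) {
  y <- as.numeric(outcome)
  observed <- auc_mw(cv_logistic_probs(X, y, ridge), y)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(b) {
    yp <- sample(y)
    tryCatch(auc_mw(cv_logistic_probs(X, yp, ridge), yp),
             error = function(e) -Inf)
  }, numeric(1))
  structure(list(observed = observed, null = null,
                 p_value = (1 + sum(null >= observed)) / (n_perm + 1),
                 n_permutations = n_perm, statistic = "cvAUC", seed = seed),
            class = "permutation_result")
}

# Mann-Whitney AUC: (concordant + 0.5 * ties) / (n1 * n0), via midranks
auc_mw <- function(scores, truth) {
  truth <- as.numeric(truth)
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) {
    stop_sepsimet("sepsimet_invalid_argument",
                  "both classes must be present")
  }
  r <- rank(scores)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve, AUC and bootstrap confidence interval
#'
#' The AUC uses the Mann-Whitney pairwise formulation
#' (concordant + 0.5 x ties over all case-control pairs, computed via
#' midranks, identical to the area under the threshold-sweep curve). The CI
#' is a stratified percentile bootstrap (cases and controls resampled
#' separately).
#'
#' @param scores Numeric risk scores (higher = more case-like).
#' @param truth 0/1 vector.
#' @param conf_level CI level, default 0.95.
#' @param n_boot Bootstrap resamples, default 2000.
#' @param seed Seed for the bootstrap.
#' @return A `roc_result`: `thresholds`, `sensitivity`, `specificity`
#'   (curve in threshold order), `auc`, `ci` (level, lower, upper),
#'   `method`.
#' @export
roc_curve <- function(scores, truth, conf_level = 0.95, n_boot = 2000,
                      seed = 1) {
  truth <- as.numeric(truth)
  auc <- auc_mw(scores, truth)  # errors if single class
  thr <- c(-Inf, sort(unique(scores)), Inf)
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  sens <- vapply(thr, function(t) sum(scores >= t & truth == 1) / n1,
                 numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & truth == 0) / n0,
                 numeric(1))
  set.seed(seed)
  i1 <- which(truth == 1); i0 <- which(truth == 0)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(i1, n1, replace = TRUE), sample(i0, n0, replace = TRUE))
    auc_mw(scores[idx], truth[idx])
  }, numeric(1))
  alpha <- 1 - conf_level
  ci <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                        type = 6)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc,
                 ci = c(level = conf_level,
                        lower = min(ci[1], auc), upper = max(ci[2], auc)),
                 n_boot = n_boot,
                 method = "Mann-Whitney AUC, stratified percentile bootstrap CI"),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC %.3f (%g%% CI %.3f-%.3f), %s>\n",
              x$auc, 100 * x$ci[["level"]], x$ci[["lower"]], x$ci[["upper"]],
              x$method))
  invisible(x)
}

#' Diagnostic indices at an operating threshold
#'
#' Sensitivity, specificity, PPV, NPV and accuracy with Wilson 95% CIs, at
#' the threshold maximising Youden's J (default) or a fixed value. Scores at
#' or above the threshold are called positive.
#'
#' @param scores Numeric risk scores.
#' @param truth 0/1 vector.
#' @param threshold `"youden"` or a numeric cut.
#' @param conf_level CI level for the Wilson intervals.
#' @return A `diagnostic_indices` data.frame: one row per index with
#'   `estimate`, `lower`, `upper`, plus the threshold as an attribute.
#' @export
diagnostic_indices <- function(scores, truth, threshold = "youden",
                               conf_level = 0.95) {
  truth <- as.numeric(truth)
  if (identical(threshold, "youden")) {
    cand <- c(-Inf, sort(unique(scores)))
    j <- vapply(cand, function(t) {
      sens <- sum(scores >= t & truth == 1) / sum(truth == 1)
      spec <- sum(scores < t & truth == 0) / sum(truth == 0)
      sens + spec - 1
    }, numeric(1))
    threshold <- cand[which.max(j)]
  }
  pos <- scores >= threshold
  tp <- sum(pos & truth == 1); fn <- sum(!pos & truth == 1)
  tn <- sum(!pos & truth == 0); fp <- sum(pos & truth == 0)
  idx <- list(sensitivity = c(tp, tp + fn),
              specificity = c(tn, tn + fp),
              PPV = c(tp, tp + fp),
              NPV = c(tn, tn + fn),
              accuracy = c(tp + tn, tp + fn + tn + fp))
  out <- do.call(rbind, lapply(names(idx), function(nm) {
    k <- idx[[nm]][1]; n <- idx[[nm]][2]
    est <- if (n > 0) k / n else NA_real_
    ci <- if (n > 0) wilson_ci(k, n, conf_level) else c(NA_real_, NA_real_)
    data.frame(index = nm, estimate = est, lower = ci[[1]], upper = ci[[2]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "confusion") <- c(TP = tp, FN = fn, TN = tn, FP = fp)
  class(out) <- c("diagnostic_indices", "data.frame")
  out
}

#' Compare two risk scores on the same subjects
#'
#' Paired stratified bootstrap of the AUC difference (score A minus score
#' B): the same resampled subjects feed both AUCs, giving a percentile CI
#' and a two-sided bootstrap p value for the difference.
#'
#' @param scores_a,scores_b Risk scores for the same subjects, same order.
#' @param truth 0/1 vector.
#' @param n_boot Bootstrap resamples.
#' @param conf_level CI level.
#' @param seed Seed.
#' @return List: `auc_a`, `auc_b`, `delta`, `ci`, `p_value`, `n_boot`.
#' @export
compare_scores <- function(scores_a, scores_b, truth, n_boot = 2000,
                           conf_level = 0.95, seed = 1) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(truth)) {
    stop_sepsimet("sepsimet_alignment_error",
                  "scores and truth must describe the same subjects")
  }
  truth <- as.numeric(truth)
  auc_a <- auc_mw(scores_a, truth); auc_b <- auc_mw(scores_b, truth)
  delta <- auc_a - auc_b
  set.seed(seed)
  i1 <- which(truth == 1); i0 <- which(truth == 0)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
    auc_mw(scores_a[idx], truth[idx]) - auc_mw(scores_b[idx], truth[idx])
  }, numeric(1))
  alpha <- 1 - conf_level
  ci <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                        type = 6)
  p <- 2 * min(mean(boot <= 0) + 1 / (n_boot + 1),
               mean(boot >= 0) + 1 / (n_boot + 1))
  list(auc_a = auc_a, auc_b = auc_b, delta = delta,
       ci = c(level = conf_level, lower = ci[1], upper = ci[2]),
       p_value = min(1, p), n_boot = n_boot)
}

#' SOFA-based logistic mortality score
#'
#' Logistic regression of the outcome on the SOFA score at 0h and 24h —
#' the same machinery as the metabolomic score, for a fair comparison.
#'
#' @param SOFA_0h,SOFA_24h Integer SOFA scores in [0, 24], one per subject.
#' @param outcome 0/1 vector (1 = non-survivor).
#' @return List: `probabilities`, `model`.
#' @export
sofa_score_model <- function(SOFA_0h, SOFA_24h, outcome) {
  if (any(c(SOFA_0h, SOFA_24h) < 0 | c(SOFA_0h, SOFA_24h) > 24)) {
    stop_sepsimet("sepsimet_invalid_argument",
                  "SOFA scores must lie in [0, 24]")
  }
  X <- cbind(SOFA_0h = SOFA_0h, SOFA_24h = SOFA_24h)
  if (stats::var(SOFA_0h) == 0 && stats::var(SOFA_24h) == 0) {
    # constant predictors: non-informative model, probability = prevalence
    model <- structure(list(coefficients = c(`(Intercept)` =
                                               stats::qlogis(mean(outcome)),
                                             SOFA_0h = 0, SOFA_24h = 0),
                            converged = TRUE, n_iterations = 0L,
                            separation = FALSE, ridge = 0),
                       class = "logistic_model")
  } else {
    model <- logistic_fit(X, outcome)
  }
  list(probabilities = predict(model, X), model = model)
}

#' Cross-validated SOFA score probabilities
#'
#' @inheritParams sofa_score_model
#' @return Out-of-fold probability per subject (leave-one-out).
#' @export
cv_sofa_score <- function(SOFA_0h, SOFA_24h, outcome) {
  X <- cbind(SOFA_0h = SOFA_0h, SOFA_24h = SOFA_24h)
  cv_logistic_probs(X, as.numeric(outcome), ridge = 0.01)
}
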