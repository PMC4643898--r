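# Logistic scoring, Mann-Whitney ROC, diagnostic indices, score comparison.

test_that("a saturated binary-predictor fit matches the closed-form odds", {
  # 2x2 table: x=0 -> 4/18 events, x=1 -> 8/42 non-events... use fixed counts
  # events: x=1 in 8 of 12; x=0 in 4 of 48 -> slope log((8*44)/(4*4))
  x <- c(rep(1, 12), rep(0, 48))
  y <- c(rep(1, 8), rep(0, 4), rep(1, 4), rep(0, 44))
  fit <- logistic_fit(matrix(x, ncol = 1), y)
  slope_ref <- log((8 / 4) / (4 / 44))
  int_ref <- log(4 / 44)
  expect_lt(abs(fit$coefficients[2] - slope_ref), 1e-6)
  expect_lt(abs(fit$coefficients[1] - int_ref), 1e-6)
  probs <- predict(fit, matrix(x, ncol = 1))
  expect_equal(unname(probs[1]), 8 / 12, tolerance = 1e-6)
})

test_that("logistic fit validates its outcome coding", {
  X <- matrix(rnorm(10), ncol = 1)
  expect_error(logistic_fit(X, rep(0, 10)),
               class = "sepsimet_invalid_argument")
  expect_error(logistic_fit(X, c(rep(0, 9), 2)),
               class = "sepsimet_invalid_argument")
})

test_that("complete separation is reported, and ridge rescues it", {
  X <- matrix(c(1:5, 11:15), ncol = 1)
  y <- rep(c(0, 1), each = 5)
  expect_error(logistic_fit(X, y), class = "sepsimet_nonconvergence")
  fit <- logistic_fit(X, y, ridge = 0.1)
  expect_true(fit$converged)
  expect_gt(fit$coefficients[2], 0)
})

test_that("ridge coefficients shrink toward zero as the penalty grows", {
  set.seed(1)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- as.numeric(plogis(X[, 1]) > runif(60))
  b1 <- logistic_fit(X, y, ridge = 0.01)$coefficients[-1]
  b2 <- logistic_fit(X, y, ridge = 10)$coefficients[-1]
  expect_lt(sum(b2^2), sum(b1^2))
})

test_that("the Mann-Whitney AUC matches the exhaustive pairwise count", {
  set.seed(6)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    truth <- rbinom(n, 1, 0.5)
    if (length(unique(truth)) < 2) next
    scores <- round(rnorm(n), 1)  # rounding forces ties
    expect_lt(abs(roc_curve(scores, truth, n_boot = 10)$auc -
                    brute_force_auc(scores, truth)), 1e-10)
  }
})

test_that("AUC cross-checks against pROC and known values", {
  scores <- c(0.1, 0.4, 0.35, 0.8)
  truth <- c(0, 0, 1, 1)
  r <- roc_curve(scores, truth, n_boot = 50)
  expect_equal(r$auc, 0.75, tolerance = 1e-12)
  set.seed(9)
  s2 <- rnorm(40); t2 <- rbinom(40, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(t2, s2, quiet = TRUE,
                                        direction = "<")))
  expect_lt(abs(roc_curve(s2, t2, n_boot = 10)$auc - ref), 1e-10)
})

test_that("negating the scores flips the AUC around one half", {
  set.seed(10)
  s <- rnorm(30); t <- rbinom(30, 1, 0.5)
  a1 <- roc_curve(s, t, n_boot = 10)$auc
  a2 <- roc_curve(-s, t, n_boot = 10)$auc
  expect_equal(a1 + a2, 1, tolerance = 1e-12)
})

test_that("perfectly separated scores give AUC 1 and a degenerate CI", {
  s <- c(1, 2, 3, 11, 12, 13)
  t <- rep(c(0, 1), each = 3)
  r <- roc_curve(s, t, n_boot = 200, seed = 2)
  expect_equal(r$auc, 1)
  expect_equal(unname(r$ci[["upper"]]), 1)
  # curve endpoints: (-Inf) -> sens 1/spec 0; (Inf) -> sens 0/spec 1
  expect_equal(r$sensitivity[1], 1)
  expect_equal(r$specificity[1], 0)
  expect_equal(r$sensitivity[length(r$thresholds)], 0)
  expect_equal(r$specificity[length(r$thresholds)], 1)
})

test_that("the bootstrap CI contains the point estimate and is ordered", {
  set.seed(11)
  s <- rnorm(40); t <- rbinom(40, 1, 0.3)
  r <- roc_curve(s, t, n_boot = 500, seed = 3)
  expect_lte(r$ci[["lower"]], r$auc)
  expect_gte(r$ci[["upper"]], r$auc)
  r2 <- roc_curve(s, t, n_boot = 500, seed = 3)
  expect_identical(r$ci, r2$ci)
})

test_that("single-class truth is rejected by the ROC machinery", {
  expect_error(roc_curve(rnorm(5), rep(1, 5), n_boot = 10),
               class = "sepsimet_invalid_argument")
})

test_that("diagnostic indices reproduce exact confusion fractions", {
  # construct scores/truth with TP=10, FN=2, TN=40, FP=8 at threshold 0.5
  scores <- c(rep(0.9, 10), rep(0.1, 2), rep(0.2, 40), rep(0.7, 8))
  truth <- c(rep(1, 12), rep(0, 48))
  di <- diagnostic_indices(scores, truth, threshold = 0.5)
  est <- setNames(di$estimate, di$index)
  expect_equal(unname(est["sensitivity"]), 10 / 12)
  expect_equal(unname(est["specificity"]), 40 / 48)
  expect_equal(unname(est["PPV"]), 10 / 18)
  expect_equal(unname(est["NPV"]), 40 / 42)
  expect_equal(unname(est["accuracy"]), 50 / 60)
  expect_equal(attr(di, "confusion"), c(TP = 10, FN = 2, TN = 40, FP = 8))
  # Wilson CI oracle for sensitivity
  ref <- prop.test(10, 12, correct = FALSE)$conf.int
  expect_equal(di$lower[di$index == "sensitivity"], ref[1], tolerance = 1e-9)
  expect_equal(di$upper[di$index == "sensitivity"], ref[2], tolerance = 1e-9)
})

test_that("a -Inf threshold calls everything positive", {
  scores <- rnorm(20)
  truth <- rep(c(0, 1), 10)
  di <- diagnostic_indices(scores, truth, threshold = -Inf)
  est <- setNames(di$estimate, di$index)
  expect_equal(unname(est["sensitivity"]), 1)
  expect_equal(unname(est["specificity"]), 0)
})

test_that("the Youden threshold maximises sensitivity + specificity", {
  set.seed(12)
  scores <- rnorm(30)
  truth <- rbinom(30, 1, 0.5)
  di <- diagnostic_indices(scores, truth)
  thr <- attr(di, "threshold")
  j_at <- function(t) {
    sum(scores >= t & truth == 1) / sum(truth == 1) +
      sum(scores < t & truth == 0) / sum(truth == 0) - 1
  }
  j_all <- vapply(c(-Inf, sort(unique(scores))), j_at, numeric(1))
  expect_equal(j_at(thr), max(j_all), tolerance = 1e-12)
})

test_that("comparing a score with itself gives a null difference", {
  set.seed(13)
  s <- rnorm(30); t <- rbinom(30, 1, 0.4)
  cmp <- compare_scores(s, s, t, n_boot = 200)
  expect_equal(cmp$delta, 0)
  expect_lte(cmp$ci[["lower"]], 0)
  expect_gte(cmp$ci[["upper"]], 0)
  expect_gte(cmp$p_value, 0.9)
})

test_that("compare_scores is continuous under a tiny score perturbation", {
  set.seed(14)
  s <- rnorm(30); t <- rbinom(30, 1, 0.4)
  eps <- 1e-12 * rnorm(30)
  # perturbation far below score spacing: identical ranks, identical delta
  cmp <- compare_scores(s, s + eps, t, n_boot = 100)
  expect_lt(abs(cmp$delta), 1e-6)
})

test_that("misaligned score vectors are rejected", {
  expect_error(compare_scores(rnorm(5), rnorm(6), rep(c(0, 1), 3)),
               class = "sepsimet_alignment_error")
})

test_that("SOFA trajectories separate outcomes on study-like medians", {
  set.seed(15)
  n1 <- 12; n0 <- 48
  SOFA_0h <- pmin(24, pmax(0, round(c(rnorm(n1, 11, 3), rnorm(n0, 7, 3)))))
  SOFA_24h <- pmin(24, pmax(0, round(c(rnorm(n1, 8, 3), rnorm(n0, 5, 3)))))
  outcome <- rep(c(1, 0), c(n1, n0))
  fit <- sofa_score_model(SOFA_0h, SOFA_24h, outcome)
  expect_gt(auc_mw(fit$probabilities, outcome), 0.5)
  # flipped labels flip the direction of the fitted effect
  fit_f <- sofa_score_model(SOFA_0h, SOFA_24h, 1 - outcome)
  expect_lt(auc_mw(fit_f$probabilities, outcome), 0.5)
})

test_that("constant SOFA degrades gracefully to the prevalence", {
  out <- rep(c(1, 0), c(3, 9))
  fit <- sofa_score_model(rep(8, 12), rep(8, 12), out)
  expect_equal(unname(fit$probabilities), rep(mean(out), 12))
  expect_error(sofa_score_model(c(8, 30), c(8, 8), c(0, 1)),
               class = "sepsimet_invalid_argument")
})

test_that("score predictors assemble both timepoints or baseline + delta", {
  p0 <- data.frame(sample_id = c("a", "b"), m1 = c(1, 2), m2 = c(3, 4))
  p24 <- data.frame(sample_id = c("a", "b"), m1 = c(5, 6), m2 = c(7, 8))
  X <- score_predictors(p0, p24, "both-timepoints")
  expect_identical(colnames(X), c("m1_0h", "m2_0h", "m1_24h", "m2_24h"))
  Xd <- score_predictors(p0, p24, "baseline-delta")
  expect_equal(unname(Xd[, "m1_delta"]), c(4, 4))
  bad <- p24; names(bad)[2] <- "zz"
  expect_error(score_predictors(p0, bad), class = "sepsimet_schema_error")
})

test_that("cross-validated probabilities carry no in-sample optimism", {
  # pure-noise predictors: apparent AUC is optimistic, CV AUC is not
  set.seed(16)
  reps <- vapply(1:15, function(i) {
    X <- matrix(rnorm(24 * 6), 24, 6)
    y <- rep(c(0, 1), 12)
    fit <- logistic_fit(X, y, ridge = 0.1)
    app <- auc_mw(predict(fit, X), y)
    cv <- auc_mw(cv_logistic_probs(X, y, ridge = 0.1), y)
    c(app, cv)
  }, numeric(2))
  expect_gt(mean(reps[1, ]), mean(reps[2, ]))
  expect_lt(abs(mean(reps[2, ]) - 0.5), 0.15)
})

test_that("the AUC permutation test flags an informative score", {
  set.seed(17)
  y <- rep(c(0, 1), each = 10)
  X <- cbind(y * 2 + rnorm(20, 0, 0.5), rnorm(20))
  pt <- permutation_test_auc(X, y, ridge = 0.1, n_perm = 100, seed = 1)
  expect_lte(pt$p_value, 0.05)
  expect_equal(pt$statistic, "cvAUC")
})
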