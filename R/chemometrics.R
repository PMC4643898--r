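# Multivariate core: PCA with T2/Q outlier screening, NIPALS PLS-DA,
# leave-one-out and repeated stratified k-fold cross-validation (Q2_press,
# Q2_corr, RMSECV), and the permutation overfit test.

#' Principal component analysis (SVD-based)
#'
#' Components maximise successive variance of a column-centred matrix. A
#' deterministic sign convention is applied: the largest-magnitude element of
#' each loading vector is positive.
#'
#' @param X Column-centred numeric matrix (samples x features).
#' @param k Number of components, `k <= min(nrow(X) - 1, ncol(X))`.
#' @return A `pca_model`: `loadings` (features x k, orthonormal), `scores`
#'   (samples x k), `explained_variance` (fraction per component,
#'   non-increasing), `k`, `n`.
#' @export
pca_fit <- function(X, k) {
  X <- as.matrix(X)
  if (!is_count(k) || k < 1 || k > min(nrow(X) - 1, ncol(X))) {
    stop_sepsimet("sepsimet_invalid_argument",
                  "k must be in [1, min(n-1, p)] = [1, %d]",
                  min(nrow(X) - 1, ncol(X)))
  }
  cm <- colMeans(X)
  if (max(abs(cm)) > 1e-6 * max(abs(X), 1)) {
    stop_sepsimet("sepsimet_invalid_argument",
                  "X must be column-centred (max |column mean| = %g)",
                  max(abs(cm)))
  }
  sv <- svd(X, nu = k, nv = k)
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  for (a in seq_len(k)) {  # sign convention
    j <- which.max(abs(loadings[, a]))
    if (loadings[j, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  structure(list(loadings = loadings, scores = scores,
                 explained_variance = sv$d[seq_len(k)]^2 / sum(sv$d^2),
                 singular_values = sv$d[seq_len(k)],
                 k = k, n = nrow(X)),
            class = "pca_model")
}

#' Flag multivariate outliers by Hotelling T2 and Q residuals
#'
#' A sample is flagged when its Hotelling T2 (within-model distance) exceeds
#' the F-distribution control limit at `alpha`, or its Q residual (squared
#' off-model distance) exceeds a Box chi-square moment-approximation limit.
#'
#' @param model A `pca_model` fitted on `X`.
#' @param X The column-centred matrix the model was fitted on.
#' @param alpha Confidence level in (0, 1), default 0.95.
#' @return Data.frame with `T2`, `Q`, the two control limits and logical
#'   `flag_T2`, `flag_Q`, `flag`.
#' @export
flag_outliers <- function(model, X, alpha = 0.95) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_sepsimet("sepsimet_invalid_argument", "alpha must be in (0, 1)")
  }
  X <- as.matrix(X)
  n <- nrow(X); k <- model$k
  lambda <- model$singular_values^2 / (n - 1)
  t2 <- rowSums(sweep(model$scores^2, 2, lambda, "/"))
  t2_lim <- if (n > k + 1) {
    k * (n - 1) * (n + 1) / (n * (n - k)) * stats::qf(alpha, k, n - k)
  } else Inf
  resid <- X - model$scores %*% t(model$loadings)
  q <- rowSums(resid^2)
  m <- mean(q); v <- stats::var(q)
  q_lim <- if (is.finite(v) && v > 0 && m > 0) {
    g <- v / (2 * m); h <- 2 * m^2 / v
    g * stats::qchisq(alpha, h)
  } else Inf
  data.frame(sample = rownames(X) %||% seq_len(n),
             T2 = t2, T2_limit = t2_lim, flag_T2 = t2 > t2_lim,
             Q = q, Q_limit = q_lim, flag_Q = q > q_lim,
             flag = t2 > t2_lim | q > q_lim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' PCA outlier screen on a raw feature matrix
#'
#' Centres the matrix, retains components up to `cum_var` cumulative
#' explained variance (at most n-2), and applies [flag_outliers()].
#'
#' @param X Numeric matrix (samples x features), uncentred.
#' @param cum_var Cumulative explained-variance target for the model size.
#' @param alpha Confidence level for both control limits.
#' @return The [flag_outliers()] data.frame, with the chosen `k` as an
#'   attribute.
#' @export
pca_screen <- function(X, cum_var = 0.95, alpha = 0.95) {
  X <- as.matrix(X)
  Xc <- sweep(X, 2, colMeans(X))
  k_max <- min(nrow(X) - 2, ncol(X))
  full <- svd(Xc, nu = 0, nv = 0)
  frac <- cumsum(full$d^2) / sum(full$d^2)
  k <- max(1L, min(which(frac >= cum_var), k_max))
  model <- pca_fit(Xc, k)
  out <- flag_outliers(model, Xc, alpha)
  attr(out, "k") <- k
  log_msg("INFO", "outlier screen: k=", k, ", flagged ", sum(out$flag),
          " of ", nrow(out))
  out
}

#' Fit a PLS-DA model (NIPALS, single response)
#'
#' Partial least squares regression of a binary class variable (coded 0/1,
#' centred internally) on the feature matrix, by NIPALS deflation. The
#' regression coefficient vector maps centred features to predicted class
#' values; R2Y is the in-sample fraction of class-variable variance
#' explained.
#'
#' @param X Numeric matrix (samples x features).
#' @param y Class vector: 0/1 numeric, logical, or 2-level factor.
#' @param A Number of latent components (>= 1).
#' @param center Centre `X` internally (default). Pass `FALSE` if `X` is
#'   already column-centred.
#' @return A `plsda_model`: per-component `weights`, `x_loadings`,
#'   `y_loadings`, `scores`; `coefficients`; `x_means`, `y_mean`; `R2Y`;
#'   `class_threshold`; `A` (components actually extracted).
#' @export
plsda_fit <- function(X, y, A, center = TRUE) {
  X <- as.matrix(X)
  y <- encode_class(y)
  if (length(unique(y)) < 2) {
    stop_sepsimet("sepsimet_invalid_argument",
                  "both classes must be present in y")
  }
  if (!is_count(A) || A < 1 || A > min(nrow(X) - 1, ncol(X))) {
    stop_sepsimet("sepsimet_invalid_argument",
                  "A must be in [1, min(n-1, p)] = [1, %d]",
                  min(nrow(X) - 1, ncol(X)))
  }
  x_means <- if (center) colMeans(X) else rep(0, ncol(X))
  E <- sweep(X, 2, x_means)
  y_mean <- mean(y)
  f <- y - y_mean
  tss <- sum(f^2)

  W <- P <- matrix(0, ncol(X), A)
  Tm <- matrix(0, nrow(X), A)
  q <- numeric(A)
  a_used <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(tss))) break  # residual orthogonal to X
    w <- w / nw
    t_a <- drop(E %*% w)
    tt <- sum(t_a^2)
    if (tt < .Machine$double.eps) break
    p_a <- drop(crossprod(E, t_a)) / tt
    q_a <- sum(f * t_a) / tt
    E <- E - tcrossprod(t_a, p_a)
    f <- f - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
    a_used <- a
  }
  if (a_used == 0L) {
    stop_sepsimet("sepsimet_invalid_argument",
                  "no PLS component could be extracted (X'y is zero)")
  }
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Tm <- Tm[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  coefficients <- drop(W %*% solve(crossprod(P, W), q))
  r2y <- 1 - sum(f^2) / tss
  yhat <- drop(sweep(X, 2, x_means) %*% coefficients) + y_mean
  thr <- mean(c(mean(yhat[y == 1]), mean(yhat[y == 0])))
  structure(list(weights = W, x_loadings = P, y_loadings = q, scores = Tm,
                 coefficients = coefficients, x_means = x_means,
                 y_mean = y_mean, R2Y = r2y, class_threshold = thr,
                 A = a_used),
            class = "plsda_model")
}

encode_class <- function(y) {
  if (is.factor(y) || is.character(y)) {
    lev <- sort(unique(as.character(y)))
    if (length(lev) > 2) {
      stop_sepsimet("sepsimet_invalid_argument",
                    "y must have at most 2 classes")
    }
    y <- as.numeric(as.character(y) == lev[length(lev)])
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) {
    stop_sepsimet("sepsimet_invalid_argument", "y must be coded {0, 1}")
  }
  y
}

# coefficient vectors for all nested component counts 1..A of a fitted model
pls_coef_path <- function(model) {
  lapply(seq_len(model$A), function(a) {
    W <- model$weights[, seq_len(a), drop = FALSE]
    P <- model$x_loadings[, seq_len(a), drop = FALSE]
    drop(W %*% solve(crossprod(P, W), model$y_loadings[seq_len(a)]))
  })
}

#' Predict class values from a PLS-DA model
#'
#' @param object A `plsda_model`.
#' @param newdata Feature matrix on the original (uncentred) scale.
#' @param type `"response"` for continuous predicted y, `"class"` for 0/1
#'   at the model's decision threshold.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.plsda_model <- function(object, newdata, type = c("response", "class"),
                                ...) {
  type <- match.arg(type)
  yhat <- drop(sweep(as.matrix(newdata), 2, object$x_means) %*%
                 object$coefficients) + object$y_mean
  if (type == "class") as.numeric(yhat >= object$class_threshold) else yhat
}

#' Leave-one-out cross-validation of a PLS-DA model
#'
#' All preprocessing statistics that depend on the training set (column
#' means, class mean) are recomputed inside each fold, so no information
#' leaks from the held-out sample. Reports the conventional
#' `Q2_press = 1 - PRESS/TSS` and `RMSECV` from the leave-one-out
#' predictions, plus `Q2_corr`: the signed squared correlation between the
#' class variable and out-of-fold predictions averaged over repeated
#' stratified k-fold splits (10 x 7-fold by default) — the "averaged
#' correlation" reading of Q2.
#'
#' @param X Feature matrix on the original scale (samples x features).
#' @param y Class vector (0/1, logical or 2-level factor).
#' @param A Number of PLS components.
#' @param q2_corr Compute the repeated k-fold `Q2_corr` (skippable for
#'   speed inside permutation loops).
#' @param cv_repeats,cv_folds Repeats and folds for `Q2_corr`.
#' @param seed Seed for the repeated splits.
#' @return A `cv_result`: `predictions` (out-of-fold, one per sample),
#'   `Q2_press`, `Q2_corr`, `RMSECV`, `A`, `folds` description.
#' @export
loo_cv <- function(X, y, A, q2_corr = TRUE, cv_repeats = 10, cv_folds = 7,
                   seed = 1) {
  X <- as.matrix(X)
  y <- encode_class(y)
  n <- nrow(X)
  if (n < 3) {
    stop_sepsimet("sepsimet_invalid_argument", "need >= 3 samples for LOO")
  }
  A <- min(A, n - 2, ncol(X))
  preds <- cv_predict(X, y, A, split(seq_len(n), seq_len(n)))
  press <- sum((y - preds)^2)
  tss <- sum((y - mean(y))^2)
  q2c <- NA_real_
  if (q2_corr) {
    set.seed(seed)
    reps <- vapply(seq_len(cv_repeats), function(r) {
      folds <- stratified_folds(y, cv_folds)
      p <- cv_predict(X, y, A, folds)
      rho <- suppressWarnings(stats::cor(y, p))
      if (is.na(rho)) 0 else sign(rho) * rho^2
    }, numeric(1))
    q2c <- mean(reps)
  }
  structure(list(predictions = preds,
                 Q2_press = 1 - press / tss,
                 Q2_corr = q2c,
                 RMSECV = sqrt(mean((y - preds)^2)),
                 A = A,
                 folds = sprintf(
                   "LOO%s", if (q2_corr)
                     sprintf(" + %dx stratified %d-fold (Q2_corr)",
                             cv_repeats, cv_folds) else "")),
            class = "cv_result")
}

# out-of-fold predictions for a list of test-index folds
cv_predict <- function(X, y, A, folds) {
  preds <- numeric(nrow(X))
  for (fold in folds) {
    y_tr <- y[-fold]
    if (length(unique(y_tr)) < 2) {
      log_msg("WARN", "fold with a single class in training; ",
              "predicting the training mean")
      preds[fold] <- mean(y_tr)
      next
    }
    a_fold <- min(A, length(y_tr) - 1, ncol(X))
    fit <- plsda_fit(X[-fold, , drop = FALSE], y_tr, a_fold)
    preds[fold] <- predict(fit, X[fold, , drop = FALSE])
  }
  preds
}

stratified_folds <- function(y, k) {
  idx <- seq_along(y)
  fold_of <- integer(length(y))
  for (cls in unique(y)) {
    members <- sample(idx[y == cls])
    fold_of[members] <- rep_len(seq_len(k), length(members))
  }
  split(idx, fold_of)
}

#' Permutation (random label) test for PLS-DA overfit
#'
#' Refits the full model and its cross-validation on class labels permuted
#' without replacement, building a null distribution of the chosen
#' statistic. `p = (1 + #{null >= observed}) / (n_perm + 1)`. Fit failures
#' in the null count as null failures (recorded as `-Inf`) and are logged.
#'
#' @param X Feature matrix, original scale.
#' @param y Class vector.
#' @param A PLS components.
#' @param statistic `"Q2_press"` (default: the cross-validated quantity at
#'   risk of optimism) or `"R2Y"`.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Seed.
#' @return A `permutation_result`: `observed`, `null` values, `p_value`,
#'   `n_permutations`, `statistic`, `seed`.
#' @export
permutation_test <- function(X, y, A, statistic = c("Q2_press", "R2Y"),
                             n_perm = 200, seed = 1) {
  statistic <- match.arg(statistic)
  if (!is_count(n_perm) || n_perm < 100) {
    stop_sepsimet("sepsimet_invalid_argument", "n_perm must be >= 100")
  }
  y <- encode_class(y)
  stat_fn <- function(yy) {
    if (statistic == "Q2_press") {
      loo_cv(X, yy, A, q2_corr = FALSE)$Q2_press
    } else {
      plsda_fit(X, yy, A)$R2Y
    }
  }
  observed <- stat_fn(y)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(b) {
    tryCatch(stat_fn(sample(y)), error = function(e) {
      log_msg("WARN", "null fit failure in permutation ", b, ": ",
              conditionMessage(e))
      -Inf
    })
  }, numeric(1))
  structure(list(observed = observed, null = null,
                 p_value = (1 + sum(null >= observed)) / (n_perm + 1),
                 n_permutations = n_perm, statistic = statistic,
                 seed = seed),
            class = "permutation_result")
}

#' Choose the number of PLS components by leave-one-out RMSECV
#'
#' Fits each fold once at `A_max` and reads nested-component predictions
#' from the same fit. Ties are broken toward the smaller model.
#'
#' @param X Feature matrix, original scale.
#' @param y Class vector.
#' @param A_max Largest component count to consider.
#' @return List: `A` (chosen), `RMSECV` (per candidate A).
#' @export
select_components <- function(X, y, A_max = 5) {
  X <- as.matrix(X)
  y <- encode_class(y)
  n <- nrow(X)
  A_max <- min(A_max, n - 2, ncol(X))
  preds <- matrix(NA_real_, n, A_max)
  for (i in seq_len(n)) {
    y_tr <- y[-i]
    if (length(unique(y_tr)) < 2) {
      preds[i, ] <- mean(y_tr)
      next
    }
    fit <- plsda_fit(X[-i, , drop = FALSE], y_tr, A_max)
    path <- pls_coef_path(fit)
    xi <- X[i, ] - fit$x_means
    preds[i, ] <- vapply(path, function(b) sum(xi * b) + fit$y_mean,
                         numeric(1))
    if (fit$A < A_max) {  # later components unavailable: carry forward
      preds[i, seq(fit$A + 1, A_max)] <- preds[i, fit$A]
    }
  }
  rmsecv <- sqrt(colMeans((y - preds)^2))
  list(A = which.min(rmsecv), RMSECV = rmsecv)
}

#' Ranked PLS-DA loadings report
#'
#' The discriminant metabolite regions were identified in the source
#' workflow by inspecting loadings; this report ranks features by the
#' absolute regression coefficient (descending).
#'
#' @param model A `plsda_model`.
#' @param feature_names Optional names (e.g. bin left edges).
#' @return Data.frame: `feature`, `coefficient`, `weight1` (first-component
#'   weight), ordered by `abs(coefficient)`.
#' @export
rank_loadings <- function(model, feature_names = NULL) {
  p <- length(model$coefficients)
  nm <- feature_names %||% sprintf("f%04d", seq_len(p))
  out <- data.frame(feature = nm,
                    coefficient = model$coefficients,
                    weight1 = model$weights[, 1],
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$coefficient)), ]
  rownames(out) <- NULL
  out
}
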