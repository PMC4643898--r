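# PCA, outlier control limits, NIPALS PLS-DA, cross-validation, permutation.

center_cols <- function(X) sweep(X, 2, colMeans(X))

test_that("a rank-one matrix puts all variance on the first component", {
  set.seed(1)
  u <- rnorm(12); v <- rnorm(5)
  X <- center_cols(tcrossprod(u, v))
  m <- pca_fit(X, 1)
  expect_lt(abs(m$explained_variance[1] - 1), 1e-10)
  # reconstruction from one component is exact for a rank-one matrix
  expect_lt(max(abs(X - m$scores %*% t(m$loadings))), 1e-8)
})

test_that("PCA agrees with the eigendecomposition of the covariance", {
  set.seed(4)
  X <- center_cols(matrix(rnorm(6 * 4), 6, 4))
  m <- pca_fit(X, 3)
  eig <- eigen(cov(X), symmetric = TRUE)
  # eigenvalues of S = d^2/(n-1)
  expect_lt(max(abs(m$singular_values^2 / (nrow(X) - 1) -
                      eig$values[1:3])), 1e-9)
  # loadings equal eigenvectors up to sign
  for (a in 1:3) {
    d <- min(max(abs(m$loadings[, a] - eig$vectors[, a])),
             max(abs(m$loadings[, a] + eig$vectors[, a])))
    expect_lt(d, 1e-9)
  }
})

test_that("loadings are orthonormal and scores orthogonal", {
  set.seed(5)
  X <- center_cols(matrix(rnorm(20 * 8), 20, 8))
  m <- pca_fit(X, 4)
  expect_lt(max(abs(crossprod(m$loadings) - diag(4))), 1e-10)
  G <- crossprod(m$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("pca_fit validates k and centring", {
  X <- center_cols(matrix(rnorm(5 * 3), 5, 3))
  expect_error(pca_fit(X, 5), class = "sepsimet_invalid_argument")
  expect_error(pca_fit(X + 10, 2), class = "sepsimet_invalid_argument")
})

structured_cloud <- function(seed, n = 30, p = 40, rank = 3, noise = 0.3) {
  set.seed(seed)
  Tm <- matrix(rnorm(n * rank), n, rank)
  P <- matrix(rnorm(p * rank), p, rank)
  Tm %*% t(P) + matrix(rnorm(n * p, 0, noise), n, p)
}

test_that("a planted 10x outlier is flagged and a clean cloud mostly is not", {
  for (s in c(7, 8, 9)) {
    X <- structured_cloud(s)
    X[13, ] <- X[13, ] * 10
    expect_true(pca_screen(X)$flag[13])
  }
  # nearly nothing is flagged at an extreme confidence level
  res_hi <- pca_screen(structured_cloud(10), alpha = 0.999999)
  expect_lte(sum(res_hi$flag), 1)
})

test_that("null flag rate sits in the expected union band", {
  rates <- vapply(1:60, function(s) mean(pca_screen(structured_cloud(s))$flag),
                  numeric(1))
  # union of two ~5% tests: roughly 5-10%, allow +-3% sampling slack
  expect_gt(mean(rates), 0.02)
  expect_lt(mean(rates), 0.13)
})

test_that("one-component PLS weights are the normalized covariance X'y", {
  set.seed(2)
  X <- matrix(rnorm(14 * 6), 14, 6)
  y <- rep(c(0, 1), 7)
  m <- plsda_fit(X, y, A = 1)
  w_ref <- crossprod(center_cols(X), y - mean(y))
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  cosine <- abs(sum(m$weights[, 1] * w_ref))
  expect_gte(cosine, 1 - 1e-10)
})

test_that("full-rank PLS reproduces ordinary least squares", {
  set.seed(3)
  X <- matrix(rnorm(20 * 4), 20, 4)
  y <- rep(c(0, 1), 10)
  m <- plsda_fit(X, y, A = 4)
  ols <- lm.fit(cbind(1, X), y)$coefficients[-1]
  expect_lt(max(abs(m$coefficients - ols)), 1e-8)
})

test_that("PLS scores are mutually orthogonal", {
  set.seed(6)
  X <- matrix(rnorm(18 * 9), 18, 9)
  y <- rep(c(0, 1), 9)
  m <- plsda_fit(X, y, A = 4)
  G <- crossprod(m$scores)
  expect_lt(max(abs(G - diag(diag(G)))) / max(diag(G)), 1e-8)
})

test_that("a well-separated dataset fits nearly perfectly", {
  d <- separable_data(n_per = 10, p = 6, gap = 10, seed = 1)
  m <- plsda_fit(d$X, d$y, A = 2)
  expect_gte(m$R2Y, 0.99)
  cls <- predict(m, d$X, type = "class")
  expect_equal(cls, d$y)
})

test_that("factor labels encode with the later sorted level as class 1", {
  d <- separable_data(seed = 2)
  lab <- factor(ifelse(d$y == 1, "survivor", "non-survivor"))
  m_num <- plsda_fit(d$X, d$y, A = 1)
  m_fac <- plsda_fit(d$X, lab, A = 1)  # "survivor" sorts last -> class 1
  expect_equal(m_fac$coefficients, m_num$coefficients, tolerance = 1e-12)
})

test_that("degenerate PLS inputs raise invalid-argument errors", {
  X <- matrix(rnorm(12), 6, 2)
  expect_error(plsda_fit(X, rep(0, 6), A = 1),
               class = "sepsimet_invalid_argument")
  expect_error(plsda_fit(X, rep(c(0, 1), 3), A = 6),
               class = "sepsimet_invalid_argument")
  expect_error(plsda_fit(X, c(0, 1, 2, 0, 1, 2), A = 1),
               class = "sepsimet_invalid_argument")
})

test_that("noise-free structure cross-validates to Q2 near 1", {
  d <- separable_data(n_per = 12, p = 5, gap = 12, seed = 4)
  cv <- loo_cv(d$X, d$y, A = 2, seed = 1)
  expect_gte(cv$Q2_press, 0.95)
  expect_gte(cv$Q2_corr, 0.9)
  # internal consistency: RMSECV^2 * n == PRESS == (1 - Q2) * TSS
  tss <- sum((d$y - mean(d$y))^2)
  expect_equal(cv$RMSECV^2 * length(d$y), (1 - cv$Q2_press) * tss,
               tolerance = 1e-12)
})

test_that("random labels give non-positive Q2 on average", {
  set.seed(8)
  q2 <- vapply(1:40, function(i) {
    X <- matrix(rnorm(16 * 8), 16, 8)
    y <- rep(c(0, 1), 8)
    loo_cv(X, y, A = 1, q2_corr = FALSE)$Q2_press
  }, numeric(1))
  expect_lte(mean(q2), 0)
})

test_that("loo_cv predictions are deterministic given the seed", {
  d <- separable_data(seed = 9)
  cv1 <- loo_cv(d$X, d$y, A = 2, seed = 42)
  cv2 <- loo_cv(d$X, d$y, A = 2, seed = 42)
  expect_identical(cv1, cv2)
})

test_that("the permutation p value uses the add-one convention", {
  d <- separable_data(n_per = 8, p = 4, gap = 15, seed = 5)
  pt <- permutation_test(d$X, d$y, A = 1, n_perm = 100, seed = 1)
  expect_gte(pt$p_value, 1 / 101)
  expect_equal(pt$n_permutations, 100)
  expect_length(pt$null, 100)
  # a strong planted effect is significant
  expect_lte(pt$p_value, 0.05)
  expect_error(permutation_test(d$X, d$y, A = 1, n_perm = 50),
               class = "sepsimet_invalid_argument")
})

test_that("select_components picks A = 1 for a one-factor dataset", {
  set.seed(10)
  hits <- 0
  for (i in 1:20) {
    t1 <- rnorm(20)
    X <- tcrossprod(t1, rnorm(6)) + matrix(rnorm(20 * 6, 0, 0.05), 20, 6)
    y <- as.numeric(t1 + rnorm(20, 0, 0.2) > 0)
    if (length(unique(y)) < 2) next
    sel <- select_components(X, y, A_max = 4)
    hits <- hits + (sel$A == 1)
  }
  expect_gte(hits, 15)
})

test_that("select_components returns the argmin of its own RMSECV curve", {
  d <- separable_data(n_per = 10, p = 6, gap = 3, seed = 12)
  sel <- select_components(d$X, d$y, A_max = 4)
  expect_equal(sel$A, unname(which.min(sel$RMSECV)))
  expect_length(sel$RMSECV, 4)
})

test_that("loading ranks order features by coefficient magnitude", {
  d <- separable_data(seed = 13)
  m <- plsda_fit(d$X, d$y, A = 2)
  rk <- rank_loadings(m, paste0("f", 1:6))
  expect_identical(rk$feature,
                   paste0("f", order(abs(m$coefficients),
                                     decreasing = TRUE)))
})
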