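# Preprocessing: referencing, bucketing, normalization, centering, exclusion.

test_that("a spectrum already peaked at 0 ppm is unchanged by referencing", {
  ax <- seq(-0.25, 2, 1e-3)
  s <- new_spectrum(ax, 3 * 0.001^2 / ((ax - 0)^2 + 0.001^2))
  expect_equal(reference_to_tsp(s)$ppm, s$ppm)
})

test_that("a deliberate TSP offset is recovered to within the grid step", {
  lib <- single_line_library(center = 1.5)
  eff <- quiet_effects()
  eff$tsp_amplitude <- 3
  ax <- seq(-0.25, 2, 5e-4)
  s <- simulate_spectrum(c(probe = 1), lib, eff, ax, seed = 1, dilution = 1)
  s_off <- new_spectrum(s$ppm + 0.013, s$intensity, s$sample_id)
  ref <- reference_to_tsp(s_off)
  tsp_at <- ref$ppm[which.max(ref$intensity[ref$ppm < 0.3])]
  expect_lt(abs(tsp_at), 5e-4 + 1e-12)
  expect_lt(abs((ref$ppm[1] - s_off$ppm[1]) + 0.013), 5e-4 + 1e-12)
})

test_that("a flat or empty reference window raises a referencing failure", {
  ax <- seq(-0.25, 2, 1e-3)
  s <- new_spectrum(ax, rep(0, length(ax)))
  expect_error(reference_to_tsp(s), class = "sepsimet_referencing_failure")
  s2 <- new_spectrum(seq(1, 2, 1e-3), rep(1, 1001))
  expect_error(reference_to_tsp(s2), class = "sepsimet_referencing_failure")
})

test_that("default bucketing yields 1900 buckets", {
  ax <- seq(0.4, 10.05, 5e-4)
  s <- new_spectrum(ax, rep(1, length(ax)))
  expect_length(bin_spectrum(s), 1900)
})

test_that("a constant spectrum buckets to intensity times width", {
  ax <- seq(0.4, 10.05, 5e-4)
  s <- new_spectrum(ax, rep(2.5, length(ax)))
  bins <- bin_spectrum(s)
  expect_lt(max(abs(bins - 2.5 * 0.005)) / (2.5 * 0.005), 1e-12)
})

test_that("bucket sums conserve the full trapezoidal integral", {
  set.seed(10)
  for (i in 1:5) {
    ax <- seq(0.5, 10, 1e-3)
    y <- rnorm(length(ax)) + 5 * sin(ax)
    s <- new_spectrum(ax, y)
    total <- pracma::trapz(ax, y)
    expect_lt(abs(sum(bin_spectrum(s)) - total) / max(abs(total), 1), 1e-9)
  }
})

test_that("an axis coarser than the bucket width is refused", {
  ax <- seq(0.4, 10.05, 0.01)
  s <- new_spectrum(ax, rep(1, length(ax)))
  expect_error(bin_spectrum(s, width = 0.005),
               class = "sepsimet_resolution_error")
  s_short <- new_spectrum(seq(1, 5, 1e-3), rep(1, 4001))
  expect_error(bin_spectrum(s_short), class = "sepsimet_range_error")
})

test_that("aliphatic normalization removes per-sample scale exactly", {
  co <- simulate_cohort(3, 2, seed = 6)
  sp <- simulate_cohort_spectra(co, seed = 6)
  m1 <- normalize_aliphatic(bin_cohort(sp))
  scaled <- lapply(sp, function(s)
    new_spectrum(s$ppm, s$intensity * 7.3, s$sample_id))
  m2 <- normalize_aliphatic(bin_cohort(scaled))
  expect_lt(max(abs(m1$values - m2$values)), 1e-12)
  # aliphatic bucket sum is exactly 1 per sample
  aliph <- m1$bin_left_edges >= 0.5 - 1e-12 & m1$bin_left_edges < 4.4 - 1e-12
  expect_equal(unname(rowSums(m1$values[, aliph])), rep(1, nrow(m1$values)),
               tolerance = 1e-12)
})

test_that("normalization shrinks dilution-driven variance in total area", {
  co <- simulate_cohort(6, 6, seed = 3)
  sp <- simulate_cohort_spectra(co, seed = 3)  # default 30% dilution CV
  m_raw <- bin_cohort(sp)
  m_norm <- normalize_aliphatic(m_raw)
  # total area over the TSP-free bucket range, before vs after
  v_raw <- var(rowSums(m_raw$values))
  v_norm <- var(rowSums(m_norm$values))
  expect_lt(v_norm / mean(rowSums(m_norm$values))^2,
            v_raw / mean(rowSums(m_raw$values))^2)
})

test_that("state transitions are enforced in pipeline order", {
  co <- simulate_cohort(2, 2, seed = 1)
  sp <- simulate_cohort_spectra(co, seed = 1)
  m <- bin_cohort(sp)
  expect_error(mean_center(m), class = "sepsimet_state_error")
  m <- normalize_aliphatic(m)
  expect_error(normalize_aliphatic(m), class = "sepsimet_state_error")
  mc <- mean_center(m)
  expect_error(normalize_aliphatic(mc), class = "sepsimet_state_error")
})

test_that("mean centering zeroes columns and is idempotent", {
  co <- simulate_cohort(2, 2, seed = 9)
  sp <- simulate_cohort_spectra(co, seed = 9)
  m <- normalize_aliphatic(bin_cohort(sp))
  # two identical rows centre to the all-zero matrix
  m_dup <- m
  m_dup$values <- m$values[c(1, 1), ]
  expect_true(all(abs(mean_center(m_dup)$values) < 1e-15))
  mc <- mean_center(m)
  expect_lt(max(abs(colMeans(mc$values))), 1e-12)
  expect_equal(mean_center(mc)$values, mc$values, tolerance = 1e-14)
  single <- m
  single$values <- m$values[1, , drop = FALSE]
  expect_error(mean_center(single), class = "sepsimet_centering_degenerate")
})

test_that("region exclusion drops the right buckets and nothing else", {
  co <- simulate_cohort(2, 2, seed = 9)
  sp <- simulate_cohort_spectra(co, seed = 9)
  m <- bin_cohort(sp)
  expect_equal(exclude_regions(m, list())$values, m$values)
  m_ex <- exclude_regions(m, list(c(4.5, 5.0)))
  expect_equal(ncol(m_ex$values), 1800)
  expect_false(any(m_ex$bin_left_edges >= 4.5 - 1e-12 &
                     m_ex$bin_left_edges < 5.0 - 1e-12))
  # surviving buckets are untouched
  keep <- !(m$bin_left_edges >= 4.5 - 1e-12 & m$bin_left_edges < 5.0 - 1e-12)
  expect_identical(m_ex$values, m$values[, keep])
})

test_that("baseline subtraction flattens a quadratic drift", {
  ax <- seq(0.5, 5, 1e-3)
  drift <- 0.3 + 0.2 * ax - 0.02 * ax^2
  peak <- 2 * 0.002^2 / ((ax - 2)^2 + 0.002^2)
  s <- subtract_baseline(new_spectrum(ax, peak + drift), degree = 2)
  off_peak <- abs(ax - 2) > 0.2
  expect_lt(max(abs(s$intensity[off_peak])), 0.02)
})
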