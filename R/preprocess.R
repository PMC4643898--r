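# Preprocessing: TSP referencing, bucketing, total-aliphatic-area
# normalization, mean centering, optional region exclusion.
#
# Pipeline order is fixed and state-checked:
#   reference -> bin -> (exclude) -> normalize -> center.
# Normalization is applied before centering (centering destroys the
# positivity the area normalization relies on); the matrix records its own
# normalization/centering state so stages cannot be applied out of order or
# twice.

#' Reference a spectrum to the TSP singlet
#'
#' Shifts the ppm axis so that the maximum-intensity point inside the search
#' window lands exactly at 0.000 ppm.
#'
#' @param s A `spectrum`.
#' @param search_window ppm interval to search, default `c(-0.2, 0.2)`.
#' @return The re-referenced `spectrum`.
#' @export
reference_to_tsp <- function(s, search_window = c(-0.2, 0.2)) {
  idx <- which(s$ppm >= search_window[1] & s$ppm <= search_window[2])
  if (!length(idx)) {
    stop_sepsimet("sepsimet_referencing_failure",
                  "TSP search window [%g, %g] outside axis range",
                  search_window[1], search_window[2])
  }
  w <- s$intensity[idx]
  if (max(w) <= 0 || diff(range(w)) == 0) {
    stop_sepsimet("sepsimet_referencing_failure",
                  "no TSP peak in window: signal flat or non-positive")
  }
  peak_ppm <- s$ppm[idx[which.max(w)]]
  new_spectrum(s$ppm - peak_ppm, s$intensity, s$sample_id)
}

#' Bin (bucket) a spectrum into fixed-width ppm buckets
#'
#' Bucket b holds the trapezoidal integral of the intensity over
#' `[low + b*width, low + (b+1)*width)`. Buckets partition `[low, high)`, so
#' the bucket sums conserve the total integral exactly.
#'
#' @param s A `spectrum` whose axis covers `[low, high]`.
#' @param low,high,width Bucket range and width in ppm
#'   (defaults 0.5, 10, 0.005: 1900 buckets).
#' @return Named numeric vector of bucket integrals; names are the left
#'   edges.
#' @export
bin_spectrum <- function(s, low = 0.5, high = 10, width = 0.005) {
  if (low >= high || width <= 0) {
    stop_sepsimet("sepsimet_invalid_argument",
                  "need low < high and width > 0")
  }
  if (s$ppm[1] > low || s$ppm[length(s$ppm)] < high) {
    stop_sepsimet("sepsimet_range_error",
                  "axis [%g, %g] does not cover bin range [%g, %g]",
                  s$ppm[1], s$ppm[length(s$ppm)], low, high)
  }
  if (mean(diff(s$ppm)) > width) {
    stop_sepsimet("sepsimet_resolution_error",
                  "axis spacing %g coarser than bin width %g",
                  mean(diff(s$ppm)), width)
  }
  n_bins <- round((high - low) / width)
  edges <- low + width * (0:n_bins)
  # augment the grid with the bin edges (linear interpolation) so the
  # per-bin trapezoids tile the full-range trapezoid exactly
  inside <- s$ppm > low & s$ppm < high
  x <- c(edges, s$ppm[inside])
  y <- c(stats::approx(s$ppm, s$intensity, xout = edges)$y,
         s$intensity[inside])
  o <- order(x)
  x <- x[o]; y <- y[o]
  cum <- cumtrapz1(x, y)
  at_edges <- cum[match(edges, x)]
  bins <- diff(at_edges)
  names(bins) <- sprintf("%.4f", edges[-length(edges)])
  bins
}

#' Assemble a binned feature matrix from a list of spectra
#'
#' @param spectra Named list of `spectrum` objects.
#' @inheritParams bin_spectrum
#' @param reference If `TRUE`, TSP-reference each spectrum first.
#' @return A `binned_matrix`: list with `values` (samples x bins),
#'   `bin_left_edges`, `bin_width`, `sample_ids`, `normalization`
#'   (`"raw"` or `"aliphatic-normalized"`) and `centering` (`"uncentered"`
#'   or `"mean-centered"`).
#' @export
bin_cohort <- function(spectra, low = 0.5, high = 10, width = 0.005,
                       reference = TRUE) {
  rows <- lapply(spectra, function(s) {
    if (reference) s <- reference_to_tsp(s)
    bin_spectrum(s, low, high, width)
  })
  values <- do.call(rbind, rows)
  rownames(values) <- names(spectra)
  m <- structure(list(values = values,
                      bin_left_edges = low + width * (0:(ncol(values) - 1)),
                      bin_width = width,
                      sample_ids = names(spectra),
                      normalization = "raw",
                      centering = "uncentered"),
                 class = "binned_matrix")
  log_msg("INFO", "binned ", nrow(values), " spectra into ", ncol(values),
          " buckets of ", width, " ppm")
  m
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat(sprintf("<binned_matrix: %d samples x %d bins (%.3g ppm), %s, %s>\n",
              nrow(x$values), ncol(x$values), x$bin_width,
              x$normalization, x$centering))
  invisible(x)
}

#' Normalize each sample to its total aliphatic spectral area
#'
#' Divides every sample's bucket row by the sum of its buckets whose left
#' edge lies in the aliphatic region (default `[0.5, 4.4)` ppm), removing
#' between-sample differences in total metabolite concentration (urine
#' dilution). Afterwards the aliphatic bucket sum is exactly 1 per sample.
#'
#' @param m A raw, uncentered `binned_matrix`.
#' @param region_low,region_high Aliphatic region bounds in ppm.
#' @return The normalized `binned_matrix`.
#' @export
normalize_aliphatic <- function(m, region_low = 0.5, region_high = 4.4) {
  if (m$normalization != "raw") {
    stop_sepsimet("sepsimet_state_error", "matrix already normalized")
  }
  if (m$centering != "uncentered") {
    stop_sepsimet("sepsimet_state_error",
                  "cannot normalize a mean-centered matrix")
  }
  in_region <- m$bin_left_edges >= region_low - 1e-12 &
    m$bin_left_edges < region_high - 1e-12
  denom <- rowSums(m$values[, in_region, drop = FALSE])
  bad <- which(denom <= 0)
  if (length(bad)) {
    stop_sepsimet("sepsimet_normalization_failure",
                  "non-positive aliphatic area for sample %s",
                  m$sample_ids[bad[1]])
  }
  m$values <- m$values / denom
  m$normalization <- "aliphatic-normalized"
  m
}

#' Mean-center the feature matrix column-wise
#'
#' @param m An aliphatic-normalized `binned_matrix` with >= 2 samples.
#' @return The centered `binned_matrix` (idempotent).
#' @export
mean_center <- function(m) {
  if (m$normalization != "aliphatic-normalized") {
    stop_sepsimet("sepsimet_state_error",
                  "normalize before centering (pipeline order)")
  }
  if (nrow(m$values) < 2) {
    stop_sepsimet("sepsimet_centering_degenerate",
                  "cannot mean-center a single-sample matrix")
  }
  m$values <- sweep(m$values, 2, colMeans(m$values))
  m$centering <- "mean-centered"
  m
}

#' Remove buckets falling in the given ppm intervals
#'
#' Typically used to drop the residual-water region (e.g. `[4.5, 5.0)`);
#' off by default in the pipeline. A bucket is removed when its left edge
#' lies in any closed-open interval.
#'
#' @param m A `binned_matrix`.
#' @param regions List of 2-vectors `c(low, high)`; empty list is identity.
#' @return The reduced `binned_matrix`.
#' @export
exclude_regions <- function(m, regions = list()) {
  if (!length(regions)) return(m)
  drop <- rep(FALSE, length(m$bin_left_edges))
  for (r in regions) {
    drop <- drop | (m$bin_left_edges >= r[1] - 1e-12 &
                      m$bin_left_edges < r[2] - 1e-12)
  }
  m$values <- m$values[, !drop, drop = FALSE]
  m$bin_left_edges <- m$bin_left_edges[!drop]
  log_msg("INFO", "excluded ", sum(drop), " bins; ", sum(!drop), " remain")
  m
}

#' Optional light polynomial baseline subtraction
#'
#' Fits a polynomial of degree <= 2 to the lower envelope of the spectrum
#' (iteratively reweighted so peaks do not pull the fit up) and subtracts
#' it. Off by default: simulated and properly acquired spectra are already
#' baseline corrected.
#'
#' @param s A `spectrum`.
#' @param degree Polynomial degree, 0-2.
#' @param n_iter Reweighting iterations.
#' @return Baseline-subtracted `spectrum`.
#' @export
subtract_baseline <- function(s, degree = 2, n_iter = 5) {
  stopifnot(degree %in% 0:2)
  x <- (s$ppm - min(s$ppm)) / diff(range(s$ppm))
  design <- cbind(1, x, x^2)[, seq_len(degree + 1), drop = FALSE]
  y <- s$intensity
  fit_y <- y
  base <- rep(0, length(y))
  for (i in seq_len(n_iter)) {
    fit <- stats::lm.fit(design, fit_y)
    base <- drop(design %*% fit$coefficients)
    fit_y <- pmin(fit_y, base)  # clamp above-baseline points down to the fit
  }
  new_spectrum(s$ppm, y - base, s$sample_id)
}
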