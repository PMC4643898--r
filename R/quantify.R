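# Metabolite quantification: region integration, Lorentzian line fitting,
# the 8-metabolite panel (region area / total aliphatic area), and the
# one-way ANOVA screen between outcome groups.

#' Default discriminant metabolite regions
#'
#' ppm bounds (closed-open) and quantification mode for the eight panel
#' metabolites. The unassigned resonance is quantified over its literature
#' region 1.40-1.45 ppm; the remaining bounds bracket the corresponding peak
#' library multiplets so generator and quantifier agree. Crowded regions
#' default to Lorentzian fitting, isolated ones to direct integration.
#' Stored as an editable CSV under `inst/extdata`.
#'
#' @return A data.frame with columns `metabolite`, `low_ppm`, `high_ppm`,
#'   `mode`.
#' @export
default_regions <- function() {
  path <- system.file("extdata", "metabolite_regions.csv",
                      package = "sepsimet")
  regions <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(regions$low_ppm < regions$high_ppm),
            all(regions$mode %in% c("integral", "lorentzian-fit")))
  regions
}

#' Integrate a spectrum over a metabolite region
#'
#' Trapezoidal integral summed over the region's intervals. The raw signed
#' integral is returned: negative noise excursions are not clipped, to avoid
#' upward bias at low signal-to-noise.
#'
#' @param s A `spectrum`.
#' @param intervals Either a 2-vector `c(low, high)` or a list of such
#'   closed-open ppm intervals.
#' @return Signed area (intensity x ppm units).
#' @export
integrate_region <- function(s, intervals) {
  if (is.numeric(intervals)) intervals <- list(intervals)
  sum(vapply(intervals, function(r) {
    trapz_interval(s$ppm, s$intensity, r[1], r[2])
  }, numeric(1)))
}

#' Fit a sum of Lorentzian lines plus a linear local baseline
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `y = b0 + b1*(x - x_mid) + sum_j A_j * h_j^2 / ((x - c_j)^2 + h_j^2)`
#' over the region. Start values come from iterative tallest-residual peak
#' picking; the analytic area of each fitted line is `A * pi * h`.
#'
#' @param s A `spectrum`.
#' @param region 2-vector `c(low, high)` ppm.
#' @param n_peaks Number of Lorentzian lines to fit.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return List with `peaks` (data.frame: `center`, `hwhm`, `amplitude`,
#'   `area`), `baseline` coefficients, total `area`, `converged` flag and
#'   `residual_norm`. Non-convergence raises a fit-failure condition
#'   carrying the residual norm; callers may fall back to
#'   [integrate_region()].
#' @export
fit_lorentzians <- function(s, region, n_peaks = 1, max_iter = 500) {
  idx <- which(s$ppm >= region[1] & s$ppm < region[2])
  if (length(idx) < 5 * n_peaks) {
    stop_sepsimet("sepsimet_invalid_argument",
                  "region [%g, %g) has %d grid points; need >= %d for %d peak(s)",
                  region[1], region[2], length(idx), 5 * n_peaks, n_peaks)
  }
  x <- s$ppm[idx]; y_raw <- s$intensity[idx]
  # condition the optimisation on a unit intensity scale; the Lorentzian
  # model is linear in amplitude and baseline, so the fit is
  # scale-equivariant. A power-of-two scale keeps the division exact, so
  # rescaled copies of a spectrum follow the same optimisation path.
  y_scale <- max(abs(y_raw))
  y_scale <- if (y_scale == 0) 1 else 2^ceiling(log2(y_scale))
  y <- y_raw / y_scale
  x_mid <- mean(range(x))
  step <- stats::median(diff(x))

  # start values: local maxima of the de-medianed signal, tallest first;
  # when the region holds fewer resolved maxima than requested lines, the
  # tallest cluster is split into offset starts (overlapped multiplets)
  yc <- y - stats::median(y)
  n <- length(yc)
  is_max <- c(FALSE, yc[2:(n - 1)] > yc[1:(n - 2)] &
                yc[2:(n - 1)] >= yc[3:n], FALSE)
  peaks_found <- which(is_max & yc > 0.1 * max(yc))
  peaks_found <- peaks_found[order(-yc[peaks_found])]
  # half-width at half max of the tallest feature as the linewidth guess
  k_top <- if (length(peaks_found)) peaks_found[1] else which.max(yc)
  half <- yc[k_top] / 2
  left <- k_top; while (left > 1 && yc[left] > half) left <- left - 1
  right <- k_top; while (right < n && yc[right] > half) right <- right + 1
  fw <- max((x[right] - x[left]), 2 * step)
  hwhm_guess <- max(fw / 2 / max(1, ceiling(n_peaks / max(1, length(peaks_found)))),
                    step)
  centers0 <- x[utils::head(peaks_found, n_peaks)]
  if (length(centers0) < n_peaks) {
    need <- n_peaks - length(centers0)
    anchor <- x[k_top]
    offs <- hwhm_guess * rep(seq_len(ceiling(need / 2)), each = 2,
                             length.out = need) * rep(c(-1, 1),
                                                      length.out = need)
    centers0 <- c(centers0, pmin(pmax(anchor + offs, region[1]), region[2]))
  }
  amps0 <- pmax(yc[vapply(centers0, function(cc) which.min(abs(x - cc)),
                          integer(1))], 1e-12)
  hwhm0 <- rep(hwhm_guess, n_peaks)

  par_names <- c(paste0("c", seq_len(n_peaks)), paste0("lh", seq_len(n_peaks)),
                 paste0("a", seq_len(n_peaks)), "b0", "b1")
  start <- stats::setNames(
    c(centers0, log(hwhm0), amps0, stats::median(y), 0), par_names)
  lower <- stats::setNames(
    c(rep(region[1], n_peaks), rep(log(step), n_peaks),
      rep(0, n_peaks), -Inf, -Inf), par_names)
  upper <- stats::setNames(
    c(rep(region[2], n_peaks), rep(log(region[2] - region[1]), n_peaks),
      rep(Inf, n_peaks), Inf, Inf), par_names)

  model_fn <- function(p) {
    yhat <- p[["b0"]] + p[["b1"]] * (x - x_mid)
    for (j in seq_len(n_peaks)) {
      h <- exp(p[[paste0("lh", j)]])
      yhat <- yhat + p[[paste0("a", j)]] * h^2 /
        ((x - p[[paste0("c", j)]])^2 + h^2)
    }
    yhat
  }
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) y - model_fn(as.list(p)),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = 1e-13,
                                         ptol = 1e-13))
  converged <- fit$info %in% 1:4
  residual_norm <- sqrt(sum(fit$fvec^2))
  if (!converged) {
    stop_sepsimet("sepsimet_fit_failure",
                  "Lorentzian fit did not converge (info=%d, residual norm %g)",
                  fit$info, residual_norm)
  }
  p <- as.list(fit$par)
  peaks <- data.frame(
    center = vapply(seq_len(n_peaks), function(j) p[[paste0("c", j)]],
                    numeric(1)),
    hwhm = vapply(seq_len(n_peaks), function(j) exp(p[[paste0("lh", j)]]),
                  numeric(1)),
    amplitude = y_scale * vapply(seq_len(n_peaks),
                                 function(j) p[[paste0("a", j)]],
                                 numeric(1)))
  peaks$area <- peaks$amplitude * pi * peaks$hwhm
  peaks <- peaks[order(peaks$center), ]
  rownames(peaks) <- NULL
  list(peaks = peaks,
       baseline = y_scale * c(b0 = p[["b0"]], b1 = p[["b1"]]),
       area = sum(peaks$area),
       converged = converged,
       residual_norm = y_scale * residual_norm)
}

# number of library lines expected inside a region (drives n_peaks)
region_n_peaks <- function(region, peak_library) {
  max(1L, sum(peak_library$center_ppm >= region[1] &
                peak_library$center_ppm < region[2]))
}

#' Quantify the metabolite panel for one spectrum
#'
#' Each level is the region area divided by the trapezoidal integral over
#' the total aliphatic region `[0.5, 4.4)` ppm — the same denominator as the
#' feature-matrix normalization, so levels are exactly invariant to global
#' intensity scaling and urine dilution. Fit-mode regions fall back to
#' direct integration when the fit fails.
#'
#' @param s A TSP-referenced `spectrum`.
#' @param regions Region table, see [default_regions()].
#' @param peak_library Used to choose the number of lines for fit-mode
#'   regions.
#' @param aliphatic Denominator region, default `c(0.5, 4.4)`.
#' @return Named numeric vector of panel levels (one per region row).
#' @export
panel_levels <- function(s, regions = default_regions(),
                         peak_library = default_peak_library(),
                         aliphatic = c(0.5, 4.4)) {
  if (!nrow(regions)) return(stats::setNames(numeric(0), character(0)))
  denom <- trapz_interval(s$ppm, s$intensity, aliphatic[1], aliphatic[2])
  levels <- vapply(seq_len(nrow(regions)), function(i) {
    r <- c(regions$low_ppm[i], regions$high_ppm[i])
    if (regions$mode[i] == "lorentzian-fit") {
      area <- tryCatch(
        fit_lorentzians(s, r, n_peaks = region_n_peaks(r, peak_library))$area,
        sepsimet_fit_failure = function(e) {
          log_msg("WARN", "fit failed for ", regions$metabolite[i],
                  " in ", s$sample_id, "; falling back to integration")
          integrate_region(s, r)
        })
    } else {
      area <- integrate_region(s, r)
    }
    area / denom
  }, numeric(1))
  stats::setNames(levels, regions$metabolite)
}

#' Quantify the panel across a cohort of spectra
#'
#' @param spectra Named list of TSP-referenced `spectrum` objects.
#' @inheritParams panel_levels
#' @return Data.frame: `sample_id` plus one column per metabolite.
#' @export
cohort_panel <- function(spectra, regions = default_regions(),
                         peak_library = default_peak_library(),
                         aliphatic = c(0.5, 4.4)) {
  rows <- t(vapply(spectra, panel_levels, numeric(nrow(regions)),
                   regions = regions, peak_library = peak_library,
                   aliphatic = aliphatic))
  out <- data.frame(sample_id = names(spectra), rows,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  log_msg("INFO", "quantified ", nrow(out), " samples x ", nrow(regions),
          " metabolites")
  out
}

#' One-way ANOVA screen of panel levels between outcome groups
#'
#' Classical one-way F test with (k-1, N-k) degrees of freedom per
#' metabolite (equal-variance `oneway.test`); with two groups F equals the
#' squared pooled-variance t statistic. Raw p values are reported alongside
#' Benjamini-Hochberg adjusted ones.
#'
#' @param panel Data.frame from [cohort_panel()] (sample_id + levels).
#' @param outcome Character/factor group label per panel row.
#' @return Data.frame: `metabolite`, group means, `direction`
#'   (sign of non-survivor minus survivor mean where applicable),
#'   `F`, `df1`, `df2`, `p`, `p_adj`.
#' @export
anova_screen <- function(panel, outcome) {
  outcome <- as.factor(outcome)
  if (nlevels(outcome) < 2 || any(table(outcome) < 2)) {
    stop_sepsimet("sepsimet_degenerate_input",
                  "need >= 2 samples in each of >= 2 groups")
  }
  metabolites <- setdiff(names(panel), "sample_id")
  rows <- lapply(metabolites, function(m) {
    x <- panel[[m]]
    if (stats::var(x) == 0) {
      # all values equal: no between- or within-group variation, F defined 0
      ft <- list(statistic = 0,
                 parameter = c(nlevels(outcome) - 1,
                               length(x) - nlevels(outcome)),
                 p.value = 1)
    } else {
      ft <- stats::oneway.test(x ~ outcome, var.equal = TRUE)
    }
    means <- tapply(x, outcome, mean)
    direction <- if (all(c("survivor", "non-survivor") %in% levels(outcome)))
      sign(means[["non-survivor"]] - means[["survivor"]]) else NA_real_
    data.frame(metabolite = m,
               t(stats::setNames(as.numeric(means),
                                 paste0("mean_", levels(outcome)))),
               direction = direction,
               F = unname(ft$statistic),
               df1 = unname(ft$parameter[1]),
               df2 = unname(ft$parameter[2]),
               p = ft$p.value,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
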