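# Synthetic septic-cohort generator: clinical metadata, ground-truth urine
# metabolite concentrations, and phased frequency-domain 1H spectra.

PANEL_METABOLITES <- c("ethanol", "glucose", "hippurate", "unknown_1.42",
                       "methionine", "glutamine", "arginine", "phenylalanine")

#' Default urine peak library
#'
#' One row per resonance line: metabolite, role (`panel`, `background`),
#' multiplet line position (ppm), relative intensity (unitless weight,
#' proportional to proton count within the metabolite), Lorentzian
#' half-width at half-maximum (ppm), and the survivor-group mean
#' concentration in arbitrary units. Positions follow standard urine
#' assignments (HMDB-style); the library is a plain CSV under
#' `inst/extdata` so it can be edited without touching code.
#'
#' @return A data.frame with columns `metabolite`, `role`, `center_ppm`,
#'   `rel_intensity`, `hwhm_ppm`, `base_conc`.
#' @export
default_peak_library <- function() {
  path <- system.file("extdata", "peak_library.csv", package = "sepsimet")
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_peak_library(lib)
  lib
}

validate_peak_library <- function(lib) {
  req <- c("metabolite", "role", "center_ppm", "rel_intensity", "hwhm_ppm",
           "base_conc")
  missing <- setdiff(req, names(lib))
  if (length(missing)) {
    stop_sepsimet("sepsimet_invalid_argument",
                  "peak library lacks columns: %s", paste(missing, collapse = ", "))
  }
  if (any(lib$center_ppm < -0.5 | lib$center_ppm > 10.5)) {
    stop_sepsimet("sepsimet_invalid_argument",
                  "peak centers must lie within [-0.5, 10.5] ppm")
  }
  if (any(lib$rel_intensity <= 0) || any(lib$hwhm_ppm <= 0)) {
    stop_sepsimet("sepsimet_invalid_argument",
                  "relative intensities and linewidths must be positive")
  }
  invisible(lib)
}

#' Default effect model for group differences and nuisance variation
#'
#' Fold changes are non-survivor over survivor mean concentration. The eight
#' discriminant metabolites move in the directions reported for septic
#' non-survivors: ethanol, glucose, hippurate and the unassigned 1.40-1.45 ppm
#' singlet increase; methionine, glutamine, arginine and phenylalanine
#' decrease. Background metabolites have fold change 1. Magnitudes are
#' calibrated to give separable but overlapping groups.
#'
#' @param fold_changes Named numeric vector of multiplicative fold changes;
#'   defaults cover the eight panel metabolites.
#' @param between_cv Between-subject coefficient of variation of
#'   concentrations (log-normal).
#' @param within_timepoint_cor Correlation of a subject's log-concentrations
#'   across the 0h and 24h collections.
#' @param dilution_cv Coefficient of variation of the per-sample log-normal
#'   urine dilution multiplier.
#' @param shift_jitter_sd Per-sample, per-metabolite chemical-shift jitter SD
#'   in ppm.
#' @param noise_sd Additive Gaussian noise SD in intensity units.
#' @param baseline_amplitude Amplitude scale of the smooth (quadratic)
#'   baseline drift, intensity units.
#' @param tsp_amplitude Height of the TSP reference singlet at 0.0 ppm
#'   (not subject to dilution: the reference is added at fixed strength).
#' @param water_hump_amplitude Height of the broad residual-water hump near
#'   4.7 ppm; 0 disables it.
#' @return An object of class `effect_model` (a named list).
#' @export
default_effect_model <- function(fold_changes = c(
                                   ethanol = 2.2, glucose = 1.8,
                                   hippurate = 1.6, `unknown_1.42` = 2.0,
                                   methionine = 0.55, glutamine = 0.6,
                                   arginine = 0.6, phenylalanine = 0.55),
                                 between_cv = 0.35,
                                 within_timepoint_cor = 0.7,
                                 dilution_cv = 0.30,
                                 shift_jitter_sd = 0.003,
                                 noise_sd = 0.02,
                                 baseline_amplitude = 0.01,
                                 tsp_amplitude = 3,
                                 water_hump_amplitude = 0.3) {
  if (any(fold_changes <= 0)) {
    stop_sepsimet("sepsimet_invalid_argument", "fold changes must be > 0")
  }
  if (between_cv < 0 || dilution_cv < 0 || shift_jitter_sd < 0 ||
      noise_sd < 0) {
    stop_sepsimet("sepsimet_invalid_argument",
                  "CV, jitter and noise parameters must be >= 0")
  }
  structure(list(fold_changes = fold_changes,
                 between_cv = between_cv,
                 within_timepoint_cor = within_timepoint_cor,
                 dilution_cv = dilution_cv,
                 shift_jitter_sd = shift_jitter_sd,
                 noise_sd = noise_sd,
                 baseline_amplitude = baseline_amplitude,
                 tsp_amplitude = tsp_amplitude,
                 water_hump_amplitude = water_hump_amplitude),
            class = "effect_model")
}

#' Default ppm axis for simulated spectra
#'
#' 0.5-10 ppm at 5e-4 ppm steps (ten points per 0.005 ppm bucket, so binning
#' is nondegenerate), extended slightly below 0 ppm so the TSP reference
#' singlet is on-axis.
#'
#' @param low,high,step Axis bounds and spacing in ppm.
#' @return Numeric vector of ppm values, strictly increasing.
#' @export
default_axis <- function(low = -0.25, high = 10, step = 5e-4) {
  seq(low, high, by = step)
}

# Table 1 group medians for the SOFA trajectories (0h / 24h / 72h)
sofa_group_medians <- function() {
  list(survivor = c(7, 5, 3.5), `non-survivor` = c(11, 8, 6.5))
}

#' Simulate a septic cohort's metadata and ground-truth concentrations
#'
#' Draws one subject per patient with a 30-day outcome label, SOFA scores at
#' 0h/24h/72h whose underlying group medians default to the study cohort's
#' (survivors 7/5/3.5, non-survivors 11/8/6.5), demographics, and per-subject
#' urinary metabolite concentrations at two collections (0h, 24h).
#' Concentrations are log-normal around the group mean (survivor base
#' concentration times the fold change for non-survivors), with the stated
#' between-subject CV and a within-subject correlation across timepoints.
#' The log-normal is mean-parameterised, so group sample-mean ratios converge
#' to the configured fold changes.
#'
#' @param n_survivor,n_nonsurvivor Subjects per outcome group (each >= 2).
#' @param effects An [default_effect_model()] object.
#' @param peak_library Peak library supplying metabolite names and survivor
#'   base concentrations.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A `cohort_table` data.frame with one row per sample
#'   (subject x timepoint): `sample_id`, `subject_id`, `timepoint`,
#'   `outcome`, `SOFA_0h`, `SOFA_24h`, `SOFA_72h`, `age`, `sex`, and
#'   ground-truth concentrations in columns `conc.<metabolite>`.
#' @export
simulate_cohort <- function(n_survivor = 48, n_nonsurvivor = 12,
                            effects = default_effect_model(),
                            peak_library = default_peak_library(),
                            seed = 1) {
  if (!is_count(n_survivor) || !is_count(n_nonsurvivor) ||
      n_survivor < 2 || n_nonsurvivor < 2) {
    stop_sepsimet("sepsimet_invalid_argument",
                  "group sizes must be integers >= 2 (got %s, %s)",
                  n_survivor, n_nonsurvivor)
  }
  set.seed(seed)
  n <- n_survivor + n_nonsurvivor
  outcome <- rep(c("survivor", "non-survivor"), c(n_survivor, n_nonsurvivor))
  subject_id <- sprintf("S%03d", seq_len(n))

  meta_names <- unique(peak_library$metabolite)
  base <- vapply(meta_names, function(m) {
    peak_library$base_conc[match(m, peak_library$metabolite)]
  }, numeric(1))
  fc <- rep(1, length(meta_names))
  names(fc) <- meta_names
  known <- intersect(names(effects$fold_changes), meta_names)
  fc[known] <- effects$fold_changes[known]

  sdlog <- sqrt(log(1 + effects$between_cv^2))
  rho <- sqrt(max(0, min(1, effects$within_timepoint_cor)))

  medians <- sofa_group_medians()
  sofa <- matrix(NA_integer_, n, 3,
                 dimnames = list(NULL, c("SOFA_0h", "SOFA_24h", "SOFA_72h")))
  severity <- stats::rnorm(n)
  for (j in 1:3) {
    mu <- vapply(outcome, function(o) medians[[o]][j], numeric(1))
    raw <- mu + 3 * (0.7 * severity + sqrt(1 - 0.7^2) * stats::rnorm(n))
    sofa[, j] <- pmin(24L, pmax(0L, as.integer(round(raw))))
  }
  age_mu <- ifelse(outcome == "survivor", 60, 65)
  age <- pmin(95L, pmax(18L, as.integer(round(stats::rnorm(n, age_mu, 15)))))
  sex_p <- ifelse(outcome == "survivor", 0.667, 0.583)
  sex <- ifelse(stats::runif(n) < sex_p, "male", "female")

  # subject-level random effect shared by the two collections
  z_subj <- matrix(stats::rnorm(n * length(meta_names)), n)
  rows <- vector("list", 2L * n)
  for (tp_idx in 1:2) {
    tp <- c("0h", "24h")[tp_idx]
    eps <- matrix(stats::rnorm(n * length(meta_names)), n)
    logc <- matrix(0, n, length(meta_names))
    for (k in seq_along(meta_names)) {
      mu_g <- base[k] * ifelse(outcome == "non-survivor", fc[k], 1)
      logc[, k] <- log(mu_g) - sdlog^2 / 2 +
        sdlog * (rho * z_subj[, k] + sqrt(1 - rho^2) * eps[, k])
    }
    conc <- exp(logc)
    colnames(conc) <- paste0("conc.", meta_names)
    rows[[tp_idx]] <- data.frame(
      sample_id = paste0(subject_id, "_", tp),
      subject_id = subject_id,
      timepoint = tp,
      outcome = outcome,
      sofa, age = age, sex = sex,
      conc,
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  cohort <- rbind(rows[[1]], rows[[2]])
  cohort <- cohort[order(cohort$subject_id, cohort$timepoint), ]
  rownames(cohort) <- NULL
  class(cohort) <- c("cohort_table", "data.frame")
  attr(cohort, "effects") <- effects
  log_msg("INFO", "simulated cohort: ", n, " subjects, ", nrow(cohort),
          " samples")
  cohort
}

# Lorentzian mixture evaluated on an axis; each line truncated to a window
# of +/- trunc_hwhm half-widths (tail mass lost < 2/(pi*trunc_hwhm)).
lorentzian_mixture <- function(axis, centers, heights, hwhms,
                               trunc_hwhm = 300) {
  y <- numeric(length(axis))
  for (i in seq_along(centers)) {
    half <- max(trunc_hwhm * hwhms[i], 0.3)
    lo <- findInterval(centers[i] - half, axis) + 1L
    hi <- findInterval(centers[i] + half, axis)
    lo <- max(1L, min(lo, length(axis)))
    hi <- min(length(axis), max(hi, 0L))
    if (lo > hi) next
    idx <- lo:hi
    d <- axis[idx] - centers[i]
    y[idx] <- y[idx] + heights[i] * hwhms[i]^2 / (d^2 + hwhms[i]^2)
  }
  y
}

#' Simulate one phased, baseline-corrected urine spectrum
#'
#' Intensity = dilution x sum over metabolites of concentration-scaled
#' Lorentzian multiplets (line positions jittered per metabolite), plus a
#' smooth quadratic baseline, a TSP reference singlet at 0.0 ppm, an optional
#' broad residual-water hump near 4.7 ppm, and additive Gaussian noise.
#' Line height for a line of relative intensity w is `concentration * w`;
#' its area is therefore `concentration * w * pi * HWHM`, exactly linear in
#' concentration.
#'
#' @param concentrations Named non-negative vector, one entry per metabolite
#'   present in `peak_library`.
#' @param peak_library See [default_peak_library()].
#' @param effects See [default_effect_model()].
#' @param axis Strictly increasing ppm grid.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (so a cohort-level seed governs all samples).
#' @param sample_id Identifier stored on the spectrum.
#' @param dilution Optional fixed dilution multiplier; if `NULL` one is drawn
#'   from the effect model's log-normal.
#' @return A `spectrum` object (list with `ppm`, `intensity`, `sample_id`).
#' @export
simulate_spectrum <- function(concentrations,
                              peak_library = default_peak_library(),
                              effects = default_effect_model(),
                              axis = default_axis(),
                              seed = NULL,
                              sample_id = "sample",
                              dilution = NULL) {
  if (is.unsorted(axis, strictly = TRUE)) {
    stop_sepsimet("sepsimet_invalid_argument",
                  "ppm axis must be strictly increasing")
  }
  if (any(concentrations < 0)) {
    stop_sepsimet("sepsimet_invalid_argument",
                  "concentrations must be non-negative")
  }
  if (!is.null(seed)) set.seed(seed)
  meta_names <- unique(peak_library$metabolite)
  conc <- concentrations[meta_names]
  conc[is.na(conc)] <- 0

  # one chemical-shift jitter per metabolite (pH/ionic-strength effect)
  jitter <- stats::rnorm(length(meta_names), 0, effects$shift_jitter_sd)
  names(jitter) <- meta_names

  centers <- peak_library$center_ppm + jitter[peak_library$metabolite]
  heights <- unname(conc[peak_library$metabolite]) * peak_library$rel_intensity
  keep <- heights > 0
  signal <- lorentzian_mixture(axis, centers[keep], heights[keep],
                               peak_library$hwhm_ppm[keep])

  if (is.null(dilution)) {
    dil_sdlog <- sqrt(log(1 + effects$dilution_cv^2))
    dilution <- exp(stats::rnorm(1, -dil_sdlog^2 / 2, dil_sdlog))
  }
  intensity <- dilution * signal

  if (effects$tsp_amplitude > 0) {
    intensity <- intensity +
      lorentzian_mixture(axis, 0, effects$tsp_amplitude, 0.0012)
  }
  if (effects$water_hump_amplitude > 0) {
    amp <- effects$water_hump_amplitude * exp(stats::rnorm(1, 0, 0.2))
    intensity <- intensity + lorentzian_mixture(axis, 4.7, amp, 0.15)
  }
  if (effects$baseline_amplitude > 0) {
    b <- stats::rnorm(3, 0, effects$baseline_amplitude)
    u <- (axis - axis[1]) / (axis[length(axis)] - axis[1])
    intensity <- intensity + b[1] + b[2] * u + b[3] * u^2
  }
  if (effects$noise_sd > 0) {
    intensity <- intensity + stats::rnorm(length(axis), 0, effects$noise_sd)
  }
  new_spectrum(axis, intensity, sample_id)
}

#' Simulate spectra for every sample of a cohort
#'
#' @param cohort A `cohort_table` from [simulate_cohort()].
#' @inheritParams simulate_spectrum
#' @param seed Integer seed governing all per-sample randomness.
#' @return Named list of `spectrum` objects, one per cohort row.
#' @export
simulate_cohort_spectra <- function(cohort,
                                    peak_library = default_peak_library(),
                                    effects = default_effect_model(),
                                    axis = default_axis(),
                                    seed = 1) {
  set.seed(seed)
  conc_cols <- grep("^conc\\.", names(cohort), value = TRUE)
  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    conc <- as.numeric(cohort[i, conc_cols])
    names(conc) <- sub("^conc\\.", "", conc_cols)
    out[[i]] <- simulate_spectrum(conc, peak_library, effects, axis,
                                  seed = NULL,
                                  sample_id = cohort$sample_id[i])
  }
  names(out) <- cohort$sample_id
  log_msg("INFO", "simulated ", length(out), " spectra of length ",
          length(axis))
  out
}
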