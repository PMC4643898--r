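# Shared fixture builders. Everything is generated in code at test time.

# A single-Lorentzian spectrum on a fine grid
lorentzian_spectrum <- function(center = 1.5, amplitude = 2, hwhm = 0.001,
                                axis = seq(0.5, 3, 5e-5), noise_sd = 0,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- amplitude * hwhm^2 / ((axis - center)^2 + hwhm^2)
  if (noise_sd > 0) y <- y + rnorm(length(axis), 0, noise_sd)
  new_spectrum(axis, y, "lorentzian")
}

# An effect model with all nuisance terms switched off (pure signal)
quiet_effects <- function(...) {
  default_effect_model(dilution_cv = 0, shift_jitter_sd = 0, noise_sd = 0,
                       baseline_amplitude = 0, tsp_amplitude = 0,
                       water_hump_amplitude = 0, ...)
}

# A tiny single-line peak library for targeted spectra
single_line_library <- function(center = 1.5, hwhm = 0.001) {
  data.frame(metabolite = "probe", role = "panel", center_ppm = center,
             rel_intensity = 1, hwhm_ppm = hwhm, base_conc = 1,
             stringsAsFactors = FALSE)
}

# Exhaustive pairwise AUC: (concordant + 0.5 * ties) / (n1 * n0)
brute_force_auc <- function(scores, truth) {
  cases <- scores[truth == 1]
  controls <- scores[truth == 0]
  total <- 0
  for (a in cases) for (b in controls) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(cases) * length(controls))
}

# A well-separated two-class dataset for PLS sanity checks
separable_data <- function(n_per = 10, p = 6, gap = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p, mean = gap), n_per))
  list(X = X, y = rep(c(0, 1), each = n_per))
}
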