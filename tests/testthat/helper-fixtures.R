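# Synthetic fixtures shared across test files. All built in code; the
# noise scale is expressed as a signal-to-noise ratio against the clean
# peak so fixtures stay comparable across compositions.

amide_fixture <- function(areas, seed, snr = 100,
                          centers = c(1655, 1633, 1645), fwhm = 20,
                          baseline_slope = 5e-5, baseline_offset = 0.02) {
  tr <- components_from_areas(centers, areas, fwhm)
  clean <- gen_spectrum(spectrum_spec(tr, grid_start = 1580,
                                      grid_end = 1730))
  gen_spectrum(spectrum_spec(tr, grid_start = 1580, grid_end = 1730,
                             baseline_slope = baseline_slope,
                             baseline_offset = baseline_offset,
                             noise_sd = max(clean$absorbance) / snr,
                             seed = seed))
}

single_band_fixture <- function(center, fwhm, window, snr = Inf,
                                seed = NULL, area = 30) {
  tr <- components_from_areas(center, area, fwhm)
  clean <- gen_spectrum(spectrum_spec(tr, grid_start = window[1],
                                      grid_end = window[2]))
  noise <- if (is.finite(snr)) max(clean$absorbance) / snr else 0
  gen_spectrum(spectrum_spec(tr, grid_start = window[1],
                             grid_end = window[2],
                             noise_sd = noise, seed = seed))
}

# Minimal hand-built band_fit for tests that exercise assignment or
# classification logic directly.
fake_band_fit <- function(centers, areas, region = band_region(1618, 1696)) {
  comp <- data.frame(center = centers, fwhm = rep(20, length(centers)),
                     amplitude = areas / (20 * sqrt(pi / (4 * log(2)))),
                     lorentz_fraction = rep(0, length(centers)),
                     area = areas)
  comp <- comp[order(comp$center), ]
  rownames(comp) <- NULL
  structure(list(region = region, components = comp,
                 baseline_params = c(slope = 0, offset = 0),
                 x_center = mean(c(region$low, region$high)),
                 data = NULL, fitted_values = NULL,
                 residual_rms = 0, converged = TRUE),
            class = "band_fit")
}
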