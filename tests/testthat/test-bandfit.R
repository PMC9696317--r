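# Multi-component Levenberg-Marquardt band fitting.

test_that("noiseless single Gaussian is recovered to closed-form accuracy", {
  true_area <- 40; true_fwhm <- 18; true_center <- 1655
  s <- gen_spectrum(spectrum_spec(
    components_from_areas(true_center, true_area, true_fwhm),
    grid_start = 1580, grid_end = 1730))
  f <- fit_bands(s, band_region(1600, 1710), 1655)
  cm <- f$components
  # oracle: center = argmax, area from the closed-form moment solution
  expect_equal(cm$center, true_center, tolerance = 1e-6)
  expect_equal(cm$fwhm, true_fwhm, tolerance = 1e-6)
  expect_equal(cm$area, true_area, tolerance = 1e-6)
  expect_equal(cm$area,
               cm$amplitude * cm$fwhm * sqrt(pi / log(16)),
               tolerance = 1e-9)
  expect_true(f$converged)
  expect_lt(f$residual_rms, 1e-8)
})

test_that("carbonyl-like four-component region is recovered near-noiselessly", {
  centers <- c(1714, 1731, 1738, 1742)
  areas <- c(8, 45, 20, 27)
  tr <- components_from_areas(centers, areas, 9)
  s <- gen_spectrum(spectrum_spec(tr, grid_start = 1690, grid_end = 1770,
                                  noise_sd = 1e-4, seed = 2))
  f <- fit_bands(s, band_region(1695, 1765), centers, fwhm_init = 9,
                 fwhm_range = c(4, 20))
  expect_equal(nrow(f$components), 4)
  expect_true(all(abs(f$components$center - centers) < 1))
})

test_that("fit self-consistency: residual RMS stays at the noise level", {
  tr <- components_from_areas(c(1655, 1633), c(60, 25), 20)
  for (seed in 1:3) {
    clean <- gen_spectrum(spectrum_spec(tr, grid_start = 1580,
                                        grid_end = 1730))
    noise_sd <- max(clean$absorbance) / 100
    s <- gen_spectrum(spectrum_spec(tr, grid_start = 1580, grid_end = 1730,
                                    noise_sd = noise_sd, seed = seed))
    f <- fit_bands(s, band_region(1600, 1710), c(1633, 1655))
    expect_true(f$converged)
    expect_lt(f$residual_rms, noise_sd * 1.5)
  }
})

test_that("gauss_lorentz policy releases the Lorentzian fraction only when needed", {
  g <- seq(1600, 1710, 1)
  y <- band_profile(g, 1655, 18, 1, lorentz_fraction = 0.6)
  s <- spectrum(g, y)
  fg <- fit_bands(s, band_region(1605, 1705), 1655)
  fgl <- fit_bands(s, band_region(1605, 1705), 1655,
                   shape_policy = "gauss_lorentz")
  expect_lt(fgl$residual_rms, fg$residual_rms)
  expect_equal(fgl$components$lorentz_fraction, 0.6, tolerance = 1e-3)
  # pure Gaussian input: the policy keeps eta at zero
  s0 <- spectrum(g, band_profile(g, 1655, 18, 1))
  f0 <- fit_bands(s0, band_region(1605, 1705), 1655,
                  shape_policy = "gauss_lorentz")
  expect_equal(f0$components$lorentz_fraction, 0, tolerance = 1e-6)
})

test_that("ill-posed fits and missing centers are rejected", {
  g <- seq(1650, 1660, 1)
  s <- spectrum(g, band_profile(g, 1655, 5, 1))
  expect_error(fit_bands(s, band_region(1650, 1660), c(1652, 1654, 1656)),
               "ill-posed")
  expect_error(fit_bands(s, band_region(1650, 1660), 1700),
               "no initial center")
})

test_that("band_fit methods are mutually consistent", {
  s <- gen_spectrum(spectrum_spec(components_from_areas(1655, 40, 18),
                                  grid_start = 1580, grid_end = 1730,
                                  noise_sd = 0.005, seed = 9))
  f <- fit_bands(s, band_region(1600, 1710), 1655)
  expect_equal(predict(f), fitted(f))
  expect_equal(residuals(f), f$data$absorbance - fitted(f))
  expect_equal(sqrt(mean(residuals(f)^2)), f$residual_rms)
  cm <- coef(f)
  expect_true(all(c("center", "fwhm", "amplitude", "area") %in%
                    colnames(cm)))
  expect_output(print(f), "band_fit")
  expect_output(print(summary(f)), "residual RMS")
  # predict at arbitrary wavenumbers matches the band profile + baseline
  at <- c(1640.5, 1655, 1669.5)
  bl <- f$baseline_params["offset"] +
    f$baseline_params["slope"] * (at - f$x_center)
  expect_equal(predict(f, at),
               unname(bl + band_profile(at, cm[1, "center"], cm[1, "fwhm"],
                                        cm[1, "amplitude"])),
               tolerance = 1e-9)
})

test_that("recovery error grows with noise (fit-level monotonicity)", {
  tr <- components_from_areas(c(1633, 1655), c(25, 60), 20)
  sigmas <- c(0, 1e-4, 1e-3, 1e-2)
  med_err <- vapply(sigmas, function(sg) {
    e <- vapply(1:5, function(i) {
      s <- gen_spectrum(spectrum_spec(tr, grid_start = 1580,
                                      grid_end = 1730,
                                      noise_sd = sg, seed = 200 + i))
      f <- fit_bands(s, band_region(1600, 1710), c(1633, 1655))
      max(abs(sort(f$components$center) - c(1633, 1655)))
    }, numeric(1))
    stats::median(e)
  }, numeric(1))
  expect_true(all(diff(med_err) >= -1e-9))
})
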