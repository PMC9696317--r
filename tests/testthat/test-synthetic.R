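# Ground-truth generators: determinism, closed-form structure, and the
# round-trip contracts that make them usable as oracles elsewhere.

test_that("gen_spectrum places a noiseless band at its center and is seed-deterministic", {
  sp <- spectrum_spec(components_from_areas(1655, 40, 18),
                      grid_start = 1580, grid_end = 1730)
  s <- gen_spectrum(sp)
  expect_equal(s$wavenumbers[which.max(s$absorbance)], 1655)

  spn <- spectrum_spec(components_from_areas(1655, 40, 18),
                       grid_start = 1580, grid_end = 1730,
                       noise_sd = 0.01, seed = 42)
  expect_identical(gen_spectrum(spn)$absorbance,
                   gen_spectrum(spn)$absorbance)
  spn2 <- spectrum_spec(components_from_areas(1655, 40, 18),
                        grid_start = 1580, grid_end = 1730,
                        noise_sd = 0.01, seed = 43)
  expect_false(identical(gen_spectrum(spn)$absorbance,
                         gen_spectrum(spn2)$absorbance))
})

test_that("numerically integrated band areas reproduce the closed-form ratio", {
  # Oracle: trapezoid integration of each isolated Gaussian vs the
  # closed form a * w * sqrt(pi / ln 16).
  areas <- c(59.9, 23.2, 16.9)
  centers <- c(1655, 1633, 1645)
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  got <- vapply(1:3, function(i) {
    s <- gen_spectrum(spectrum_spec(
      components_from_areas(centers[i], areas[i], 20),
      grid_start = 1400, grid_end = 1900, grid_step = 0.5))
    trapz(s$wavenumbers, s$absorbance)
  }, numeric(1))
  expect_equal(got / got[1], areas / areas[1], tolerance = 1e-3)
  # closed form itself
  expect_equal(band_area(2, 20), 2 * 20 * sqrt(pi / log(16)))
})

test_that("spectrum_spec rejects invalid parameters", {
  comp <- components_from_areas(1655, 40, 18)
  expect_error(spectrum_spec(comp[0, ]), "non-empty")
  expect_error(spectrum_spec(data.frame(center = NaN, fwhm = 10,
                                        amplitude = 1)), "non-finite")
  expect_error(spectrum_spec(comp, grid_start = 2000, grid_end = 1000),
               "grid_start")
  expect_error(spectrum_spec(comp, grid_step = 0), "grid_step")
  expect_error(spectrum_spec(comp, noise_sd = -1), "noise_sd")
  bad <- comp; bad$fwhm <- -5
  expect_error(spectrum_spec(bad), "invalid band parameters")
})

test_that("gen_polarized round-trips anisotropy and G exactly at zero noise", {
  p <- gen_polarized(0, g_true = 1)
  expect_equal(p$I_VV, p$I_VH)            # isotropic case
  p <- gen_polarized(0.25, g_true = 1)
  expect_equal(p$I_VV / p$I_VH, 2)        # (1+2r)/(1-r) at r = 0.25
  p <- gen_polarized(0.13, g_true = 1.2)  # fluid-bilayer anisotropy
  expect_equal(anisotropy(p), 0.13)
  expect_equal(g_factor(p$I_HV, p$I_HH), 1.2)

  set.seed(7)
  for (i in 1:50) {
    r <- runif(1, -0.45, 0.95)
    g <- runif(1, 0.5, 2)
    expect_equal(suppressWarnings(anisotropy(gen_polarized(r, g))), r)
  }
  expect_error(gen_polarized(1.2), "r_true")
  expect_error(gen_polarized(0.1, g_true = 0), "g_true")
  expect_error(gen_polarized(0.1, total_intensity = -1), "total_intensity")
})

test_that("gen_release_trace follows first-order leakage and recovers CR", {
  tr0 <- gen_release_trace(release_spec(leak_rate = 0, duration = 60,
                                        sampling = 15))
  expect_equal(calcein_release(tr0), rep(0, nrow(tr0)))

  tr <- gen_release_trace(release_spec(leak_rate = 0.1, duration = 10,
                                       sampling = 10))
  expect_equal(calcein_release(tr[2, ]), 100 * (1 - exp(-1)),
               tolerance = 1e-10)

  trf <- gen_release_trace(release_spec(leak_rate = 50, duration = 10,
                                        sampling = 5))
  expect_equal(calcein_release(trf[3, ]), 100, tolerance = 1e-6)

  # nonzero initial fraction: CR is relative to what was still inside
  tri <- gen_release_trace(release_spec(leak_rate = 0.2, duration = 20,
                                        sampling = 5, I0_fraction = 0.3))
  f <- 1 - 0.7 * exp(-0.2 * tri$t)
  expect_equal(calcein_release(tri), (f - 0.3) / 0.7 * 100,
               tolerance = 1e-10)

  spn <- release_spec(leak_rate = 0.05, duration = 30, sampling = 5,
                      noise_sd = 0.02, seed = 11)
  expect_identical(gen_release_trace(spn), gen_release_trace(spn))
})

test_that("noisier spectra give worse band-center recovery (noise ladder)", {
  sigmas <- c(0, 1e-4, 1e-3, 1e-2)
  err <- vapply(sigmas, function(sg) {
    e <- vapply(1:5, function(i) {
      s <- gen_spectrum(spectrum_spec(
        components_from_areas(2924, 30, 25),
        grid_start = 2850, grid_end = 3000,
        noise_sd = sg, seed = 100 + i))
      abs(as.numeric(band_position(s, band_region(2860, 2990))) - 2924)
    }, numeric(1))
    stats::median(e)
  }, numeric(1))
  expect_true(all(diff(err) >= -1e-9))
})
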