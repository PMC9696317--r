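# Anisotropy, calcein release, Beer-Lambert, emission peaks.

test_that("g_factor is the HV/HH ratio", {
  expect_equal(g_factor(40, 40), 1)
  expect_equal(g_factor(48, 40), 1.2)
  expect_equal(g_factor(0.5, 2), 0.25)
  expect_error(g_factor(1, 0), "non-zero")
})

test_that("anisotropy implements the G-corrected formula", {
  expect_equal(anisotropy(list(I_VV = 50, I_VH = 50, I_HV = 1, I_HH = 1)),
               0)
  expect_equal(anisotropy(list(I_VV = 100, I_VH = 50, I_HV = 40,
                               I_HH = 40)), 0.25)
  # out-of-range advisory is a warning, not an error
  expect_warning(
    r <- anisotropy(list(I_VV = 10, I_VH = 50, I_HV = 1, I_HH = 1)),
    "outside the physical")
  expect_lt(r, 0)
  expect_error(anisotropy(list(I_VV = 1, I_VH = 1)), "must carry")
})

test_that("anisotropy inverts gen_polarized across its domain", {
  set.seed(13)
  for (i in 1:200) {
    r <- runif(1, -0.49, 0.99)
    g <- runif(1, 0.3, 3)
    p <- gen_polarized(r, g, total_intensity = runif(1, 1, 1000))
    expect_equal(suppressWarnings(anisotropy(p)), r, tolerance = 1e-12)
  }
})

test_that("calcein release handles the limiting and worked cases", {
  expect_equal(calcein_release(list(I_0 = 10, I_max0 = 100, I_t = 10,
                                    I_maxt = 100)), 0)
  expect_equal(calcein_release(list(I_0 = 10, I_max0 = 100, I_t = 100,
                                    I_maxt = 100)), 100)
  expect_equal(calcein_release(list(I_0 = 10, I_max0 = 100, I_t = 55,
                                    I_maxt = 100)), 50)
  expect_error(calcein_release(list(I_0 = 10, I_max0 = 100, I_t = 5,
                                    I_maxt = 10)), "zero denominator")
  expect_error(calcein_release(list(I_0 = 100, I_max0 = 100, I_t = 5,
                                    I_maxt = 200)), "exceed")
})

test_that("calcein release is scale-invariant and warns out of range", {
  tp <- list(I_0 = 12, I_max0 = 90, I_t = 47, I_maxt = 95)
  cr1 <- calcein_release(tp)
  cr2 <- calcein_release(lapply(tp, function(v) v * 7.3))
  expect_equal(cr1, cr2)
  expect_warning(
    cr <- calcein_release(list(I_0 = 10, I_max0 = 100, I_t = 105,
                               I_maxt = 100)),
    "unclipped")
  expect_gt(cr, 100)
})

test_that("CR series from a noiseless trace is monotone non-decreasing", {
  tr <- gen_release_trace(release_spec(leak_rate = 0.07, duration = 60,
                                       sampling = 5, I0_fraction = 0.05))
  cr <- calcein_release(tr)
  expect_true(all(diff(cr) >= 0))
})

test_that("Beer-Lambert is linear in absorbance and inverse in path", {
  expect_equal(dye_concentration(0.74, 74000, 1), 1e-5)
  expect_equal(dye_concentration(0), 0)
  expect_equal(dye_concentration(1.48, 74000, 2), 1e-5)
  a <- c(0.1, 0.2, 0.4)
  expect_equal(dye_concentration(2 * a), 2 * dye_concentration(a))
  expect_equal(dye_concentration(a, path = 2), dye_concentration(a) / 2)
  expect_error(dye_concentration(1, epsilon = 0), "epsilon")
  expect_error(dye_concentration(1, path = -1), "path")
})

test_that("emission_peak finds the maximum and flags degenerate cases", {
  wl <- 400:600
  iv <- band_profile(wl, 484, 60, 1000)
  s <- emission_spectrum(wl, iv)
  pk <- emission_peak(s, 420, 580)
  expect_equal(unname(pk["lambda_max"]), 484)
  expect_equal(unname(pk["intensity"]), max(iv))

  mono <- emission_spectrum(wl, rev(seq_along(wl)))
  expect_warning(pk2 <- emission_peak(mono, 400, 600), "boundary")
  expect_equal(unname(pk2["lambda_max"]), 400)

  flat <- emission_spectrum(wl, rep(5, length(wl)))
  expect_warning(pk3 <- emission_peak(flat, 450, 500), "flat")
  expect_equal(unname(pk3["lambda_max"]), 450)  # tie toward lower nm

  expect_error(emission_peak(s, 500, 450), "window_low")
})
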