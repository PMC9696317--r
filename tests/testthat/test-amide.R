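# Amide I assignment and the full secondary-structure pipeline.

test_that("a single alpha-range component maps to 100% alpha-helix", {
  ss <- assign_secondary_structure(fake_band_fit(1655, 100))
  expect_equal(ss$alpha_helix, 100)
  expect_equal(ss$beta_sheet + ss$beta_turn + ss$random_coil, 0)
  expect_equal(ss$aggregates, 0)
})

test_that("area fractions map straight to element percentages", {
  ss <- assign_secondary_structure(
    fake_band_fit(c(1633, 1645, 1655), c(23.2, 16.9, 59.9)))
  expect_equal(ss$beta_sheet, 23.2)
  expect_equal(ss$random_coil, 16.9)
  expect_equal(ss$alpha_helix, 59.9)
  expect_equal(ss$sheet_plus_turn, 23.2)
})

test_that("aggregate bands are excluded from the 100% normalization", {
  ss <- assign_secondary_structure(
    fake_band_fit(c(1624, 1633, 1645, 1655), c(10, 20.88, 15.21, 53.91)))
  expect_equal(ss$aggregates, 10)  # 10 / 100 of total area
  expect_equal(ss$alpha_helix, 100 * 53.91 / 90)
  expect_equal(ss$alpha_helix + ss$beta_sheet + ss$beta_turn +
                 ss$random_coil, 100, tolerance = 1e-10)
})

test_that("gap centers go to the nearest range, ties to lower wavenumber", {
  # 1639.5 is equidistant from beta-sheet [1628,1639) and coil [1640,1649)
  expect_equal(assign_secondary_structure(
    fake_band_fit(1639.5, 50))$beta_sheet, 100)
  # 1662 is equidistant from alpha [1650,1660) and turn [1664,1687)
  expect_equal(assign_secondary_structure(
    fake_band_fit(1662, 50))$alpha_helix, 100)
  # 1627 is equidistant from aggregates [1618,1626) and beta [1628,1639)
  expect_equal(assign_secondary_structure(
    fake_band_fit(c(1627, 1655), c(10, 90)))$aggregates, 10)
  # boundary membership is half-open: 1639 itself is outside beta-sheet
  # but at zero distance, so it still resolves to beta-sheet
  expect_equal(assign_secondary_structure(
    fake_band_fit(1639, 50))$beta_sheet, 100)
})

test_that("assignment is invariant to component order and rejects bad fits", {
  a <- assign_secondary_structure(
    fake_band_fit(c(1633, 1655, 1645), c(23.2, 59.9, 16.9)))
  b <- assign_secondary_structure(
    fake_band_fit(c(1655, 1645, 1633), c(59.9, 16.9, 23.2)))
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_error(assign_secondary_structure(fake_band_fit(1500, 10)),
               "Amide I region")
  expect_error(assign_secondary_structure(
    fake_band_fit(numeric(0), numeric(0))), "empty fit")
})

test_that("non-aggregate percentages always sum to 100", {
  set.seed(21)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    # at least one center in a conformational range; the rest anywhere
    centers <- c(runif(1, 1628, 1686), runif(k - 1, 1619, 1695))
    areas <- runif(k, 1, 50)
    ss <- assign_secondary_structure(fake_band_fit(centers, areas))
    expect_equal(ss$alpha_helix + ss$beta_sheet + ss$beta_turn +
                   ss$random_coil, 100, tolerance = 0.1)
  }
})

test_that("the full pipeline recovers generating compositions at SNR 100", {
  truth <- list(bsa = c(59.9, 23.2, 16.9), pi10 = c(52.8, 19.1, 28.0))
  for (nm in names(truth)) {
    tt <- truth[[nm]]
    res <- t(vapply(1:3, function(seed) {
      r <- amide_i_analysis(amide_fixture(tt, seed))
      c(r$alpha_helix, r$sheet_plus_turn, r$random_coil)
    }, numeric(3)))
    m <- colMeans(res)
    expect_lt(abs(m[1] - tt[1]), 2)
    expect_lt(abs(m[2] - tt[2]), 2)
    expect_lt(abs(m[3] - tt[3]), 2)
  }
})

test_that("the pipeline picks up an aggregation band when present", {
  # 12% aggregate band at 1624 on top of a BSA-like composition
  s <- amide_fixture(c(52, 20, 16, 12), seed = 4, snr = 200,
                     centers = c(1655, 1633, 1645, 1623), fwhm = 16)
  r <- amide_i_analysis(s)
  expect_gt(r$aggregates, 4)
  expect_equal(r$alpha_helix + r$beta_sheet + r$beta_turn + r$random_coil,
               100, tolerance = 0.1)
})

test_that("amide_i_analysis needs Amide I coverage", {
  s <- gen_spectrum(spectrum_spec(components_from_areas(1500, 30, 15),
                                  grid_start = 1400, grid_end = 1600))
  expect_error(amide_i_analysis(s), "outside")
})
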