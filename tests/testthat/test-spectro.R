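test_that("background correction subtracts the first spectrum at the nearest grid wavelength", {
  wl <- seq(200, 300, by = 0.33)
  tt <- seq(25, 325, by = 30)

  # identical spectra at all times -> all-zero trace
  a0 <- matrix(rep(runif(length(wl)), length(tt)), nrow = length(tt),
               byrow = TRUE)
  s <- spectral_series(wl, tt, a0)
  expect_equal(preprocess_uvvis(s, 240)$absorbance, rep(0, length(tt)))

  # constructed series A = 0.05 + eps * [Im](t): trace equals eps * [Im](t)
  eps <- 1870
  im <- seq(0, 1.4e-4, length.out = length(tt))
  a <- matrix(0.05, length(tt), length(wl))
  j <- which.min(abs(wl - 240))
  a[, j] <- 0.05 + eps * im
  s2 <- spectral_series(wl, tt, a)
  pre <- preprocess_uvvis(s2, 240)
  expect_equal(pre$absorbance, eps * im, tolerance = 1e-12)

  # nearest grid point is used and reported, no interpolation
  expect_false(240 %in% wl)
  expect_equal(pre$wavelength_used, wl[j])
  expect_lt(abs(pre$wavelength_used - 240), 0.33)

  expect_error(preprocess_uvvis(s, 199), "outside")
  expect_error(
    preprocess_uvvis(spectral_series(wl, 0, matrix(0, 1, length(wl))), 240),
    "two spectra")
})

test_that("molar absorptivity calibration recovers the Beer-Lambert slope", {
  conc <- c(0, 1e-4, 2e-4, 5e-4)
  cal <- fit_molar_absorptivity(conc, 1870 * conc)
  expect_equal(cal$epsilon, 1870, tolerance = 1e-10)
  expect_equal(cal$fit_r2, 1, tolerance = 1e-12)
  expect_true(cal$valid)

  two <- fit_molar_absorptivity(c(0, 5e-4), c(0, 0.475))
  expect_equal(two$epsilon, 950, tolerance = 1e-10)

  # all-zero absorbance: slope 0 flagged invalid
  flat <- fit_molar_absorptivity(conc, rep(0, 4))
  expect_equal(flat$epsilon, 0)
  expect_false(flat$valid)

  expect_error(fit_molar_absorptivity(rep(2e-4, 3), c(0.1, 0.2, 0.3)),
               "degenerate")
  # significant intercept warns
  expect_warning(fit_molar_absorptivity(conc, 0.2 + 1870 * conc),
                 "intercept")
})

test_that("Beer-Lambert inversion clips noise-negative values and counts them", {
  cal <- fit_molar_absorptivity(c(0, 5e-4), c(0, 0.935))
  expect_equal(cal$epsilon, 1870, tolerance = 1e-10)
  tr <- absorbance_to_concentration(c(0, 0.935, -0.001),
                                    cal, times = c(0, 30, 60))
  expect_equal(tr$concentration_M[1], 0)
  expect_equal(tr$concentration_M[2], 5e-4, tolerance = 1e-12)
  expect_equal(tr$concentration_M[3], 0)
  expect_equal(attr(tr, "metadata")$n_clipped, 1L)
  expect_identical(attr(tr, "species"), "imine")
  expect_error(absorbance_to_concentration(c(0, 1), -5, times = c(0, 30)),
               "positive")
})

test_that("round trip absorbance -> concentration is exact for noiseless input", {
  conc <- seq(0, 4.9e-4, length.out = 30)
  cal <- fit_molar_absorptivity(c(0, 5e-4), c(0, 0.475))
  tr <- absorbance_to_concentration(cal$epsilon * conc, cal,
                                    times = seq_along(conc))
  expect_equal(tr$concentration_M, conc, tolerance = 1e-14)

  # full chain: construct series from known [Im](t), recover it
  wl <- seq(200, 300, by = 0.33)
  tt <- seq(0, 7200, 30)
  im <- 5e-4 - reversible_equimolar_solution(tt, 0.058, 5.2e-5, 5e-4)
  a <- matrix(0.31, length(tt), length(wl))
  j <- which.min(abs(wl - 240))
  a[, j] <- 0.31 + 950 * im
  pre <- preprocess_uvvis(spectral_series(wl, tt, a), 240)
  rec <- absorbance_to_concentration(pre, 950)
  expect_lt(max(abs(rec$concentration_M - im)), 1e-12)
})

test_that("amine consumption trace subtracts imine from x0 with clipping", {
  tt <- c(0, 60, 7200)
  im0 <- concentration_trace(tt, rep(0, 3), species = "imine")
  am <- amine_consumption_trace(im0, 5e-4)
  expect_equal(am$concentration_M, rep(5e-4, 3))
  expect_equal(attr(am, "x0"), 5e-4)
  expect_identical(attr(am, "species"), "amine")

  im1 <- concentration_trace(tt, c(0, 1e-4, 1.43e-4), species = "imine")
  expect_equal(amine_consumption_trace(im1, 5e-4)$concentration_M[3],
               3.57e-4, tolerance = 1e-12)

  # saturation: [Im] = x0 -> 0
  im2 <- concentration_trace(tt, c(0, 5e-4, 5e-4), species = "imine")
  expect_equal(amine_consumption_trace(im2, 5e-4)$concentration_M[2:3],
               c(0, 0))

  im3 <- concentration_trace(tt, c(0, 5e-4, 5.5e-4), species = "imine")
  expect_warning(out <- amine_consumption_trace(im3, 5e-4), "exceed")
  expect_equal(out$concentration_M[3], 0)
  expect_error(amine_consumption_trace(im0, -1), "positive")
})

test_that("Schiff standard dilution arithmetic matches the published series", {
  steps <- data.frame(aliquot = c(500, 100), total = c(3000, 1000))
  stocks <- c(20e-3, 10e-3, 5e-3, 2e-3, 0.5e-3)
  finals <- schiff_standard_concentrations(stocks, steps)
  # printed: 333, 167, 83, 33 and 8 uM
  expect_equal(signif(finals * 1e6, 3), c(333, 167, 83.3, 33.3, 8.33))
  expect_equal(round(finals[1] * 1e6), 333)

  # no dilution steps: output equals stock
  expect_equal(schiff_standard_concentrations(stocks, data.frame()), stocks)

  # multiplicative homogeneity
  expect_equal(schiff_standard_concentrations(3 * stocks, steps), 3 * finals)

  expect_error(
    schiff_standard_concentrations(1e-3,
                                   data.frame(aliquot = 1100, total = 1000)),
    "exceeds")
})

test_that("degree of oxidation counts two aldehydes per oxidized unit", {
  expect_equal(degree_of_oxidation(10.1e-3, 50.5e-3), 0.10)
  expect_equal(degree_of_oxidation(0, 50e-3), 0)
  expect_equal(degree_of_oxidation(2 * 50e-3, 50e-3), 1)
  expect_error(degree_of_oxidation(3 * 50e-3, 50e-3), "DOx")
})

test_that("macromer aldehyde concentration uses one equivalent per functionalized unit", {
  # 2 wt% = 20 g/L at DOx 10% -> 10.1 mM to the printed precision
  expect_equal(macromer_aldehyde_concentration(0.02, 0.001, 0.10),
               10.1e-3, tolerance = 1e-3)
  expect_equal(macromer_aldehyde_concentration(0.02, 0.001, 0), 0)
  # linearity in mass
  expect_equal(macromer_aldehyde_concentration(0.04, 0.001, 0.10),
               2 * macromer_aldehyde_concentration(0.02, 0.001, 0.10))
  # inverting the one-per-unit convention returns the functionalization
  # degree; the Schiff-test DOx convention (two aldehydes per oxidized
  # unit) reports half of it by construction
  c_ald <- macromer_aldehyde_concentration(0.02, 0.001, 0.10)
  unit_conc <- 0.02 / (198 * 0.001)
  expect_equal(c_ald / unit_conc, 0.10, tolerance = 1e-12)
  expect_equal(degree_of_oxidation(c_ald, unit_conc), 0.05,
               tolerance = 1e-12)
})

test_that("formulation helper converts amine equivalents to cross-linker dose", {
  expect_equal(crosslinker_concentration(0.5, 10e-3), 2.5e-3)
  expect_equal(crosslinker_concentration(1, 10e-3, functionality = 1), 10e-3)
  expect_error(crosslinker_concentration(-1, 10e-3), "invalid")
})

test_that("trace and series CSV round trips preserve data and honour units", {
  dir <- withr::local_tempdir()
  tr <- concentration_trace(seq(0, 90, 30), c(5, 4, 3, 2) * 1e-4,
                            species = "amine", x0 = 5e-4)
  p <- file.path(dir, "trace.csv")
  write_concentration_trace(tr, p)
  back <- read_concentration_trace(p, species = "amine", x0 = 5e-4)
  expect_equal(back$concentration_M, tr$concentration_M, tolerance = 1e-12)

  # unit-suffixed columns convert
  writeLines(c("time_s,concentration_mM", "0,0.5", "30,0.4"),
             file.path(dir, "mm.csv"))
  mm <- read_concentration_trace(file.path(dir, "mm.csv"))
  expect_equal(mm$concentration_M, c(5e-4, 4e-4))

  s <- spectral_series(c(239.9, 240.2), c(0, 30),
                       matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2))
  ps <- file.path(dir, "series.csv")
  write_spectral_series(s, ps)
  s2 <- read_spectral_series(ps)
  expect_equal(s2$wavelengths, s$wavelengths)
  expect_equal(s2$absorbance, s$absorbance, ignore_attr = TRUE)
})
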