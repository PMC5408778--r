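test_that("spectrum files round-trip and invalid tables are rejected with the offending row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,power_umol_s_nm", "400,0.0", "401,0.0"), path)
  sp <- read_spectrum(path)
  expect_s3_class(sp, "led_spectrum")
  expect_equal(spectrum_stats(sp)$total_power, 0)

  writeLines(c("wavelength_nm,power_umol_s_nm", "500,1.0", "499,1.0"), path)
  expect_error(read_spectrum(path), "row 2")

  writeLines(c("wavelength_nm,power_umol_s_nm", "500,1.0", "501,-0.5"), path)
  expect_error(read_spectrum(path), "row 2")

  writeLines("wavelength_nm,power_umol_s_nm", path)
  expect_error(read_spectrum(path), "empty")

  sp <- gaussian_spectrum(526, 25, total_power = 2.5)
  write_spectrum(sp, path)
  sp2 <- read_spectrum(path)
  expect_equal(sp2$power_density, sp$power_density, tolerance = 1e-12)
})

test_that("a discretized unit-area Gaussian has unit total power", {
  grid <- seq(400, 650, by = 0.1)          # fine-grid quadrature oracle
  sp <- led_spectrum(grid, dnorm(grid, 526, 10))
  expect_equal(spectrum_stats(sp)$total_power, 1, tolerance = 1e-6)
})

test_that("flux conversion applies the well-geometry multiplier", {
  sp <- gaussian_spectrum(526, 25)
  fl <- flux_density_from_power(sp, 7.5e-3)
  expect_equal(fl$multiplier, 1 / (pi * 7.5e-3^2))
  expect_equal(fl$multiplier, 5.659e3, tolerance = 1e-4)
  # pi r^2 = 1 gives the identity
  fl1 <- flux_density_from_power(sp, sqrt(1 / pi))
  expect_equal(fl1$multiplier, 1, tolerance = 1e-12)
  # doubling the radius divides the multiplier by four
  fl2 <- flux_density_from_power(sp, 15e-3)
  expect_equal(fl$multiplier / fl2$multiplier, 4, tolerance = 1e-12)
  expect_error(flux_density_from_power(sp, 0), "positive")
})

test_that("unit-intensity normalization integrates to one, is idempotent, and reports the intensity", {
  sp <- gaussian_spectrum(560, 30, total_power = 3.7)
  un <- normalize_to_unit_intensity(flux_density_from_power(sp))
  expect_equal(trapz(un$wavelength, un$flux_density), 1, tolerance = 1e-9)
  expect_equal(un$intensity, 3.7 * 5658.842, tolerance = 1e-3)
  un2 <- normalize_to_unit_intensity(un)
  expect_equal(un2$flux_density, un$flux_density, tolerance = 1e-12)
  zero <- led_spectrum(c(400, 401), c(0, 0))
  expect_error(normalize_to_unit_intensity(zero), "positive")
})

test_that("spectrum statistics: centroid, FWHM, delta spike, multimodal flag", {
  sp <- gaussian_spectrum(526, 2 * sqrt(2 * log(2)) * 10)  # sigma = 10 nm
  st <- spectrum_stats(sp)
  expect_equal(st$centroid_wavelength, 526, tolerance = 1e-3)
  expect_equal(st$fwhm, 23.548, tolerance = 1e-3)          # 2 sqrt(2 ln 2) sigma
  expect_false(st$multimodal)

  grid <- common_grid()
  spike <- led_spectrum(grid, as.numeric(grid == 600))
  st2 <- spectrum_stats(spike)
  expect_equal(st2$centroid_wavelength, st2$peak_wavelength)

  bimodal <- led_spectrum(grid, dnorm(grid, 450, 10) + dnorm(grid, 650, 10))
  expect_true(spectrum_stats(bimodal)$multimodal)
  expect_gt(spectrum_stats(bimodal)$fwhm, 150)   # outermost crossing span
})

test_that("transmission filters multiply pointwise and respect [0,1]", {
  sp <- gaussian_spectrum(550, 100)
  expect_equal(apply_filter(sp, rep(1, length(sp$wavelength)))$power_density,
               sp$power_density)
  expect_equal(sum(apply_filter(sp, rep(0, length(sp$wavelength)))$power_density), 0)
  box <- as.numeric(sp$wavelength >= 500 & sp$wavelength <= 600)
  filtered <- apply_filter(sp, box)
  inband <- trapz(sp$wavelength, sp$power_density * box)
  expect_equal(spectrum_stats(filtered)$total_power, inband, tolerance = 1e-12)
  expect_error(apply_filter(sp, rep(1.5, length(sp$wavelength))), "\\[0, 1\\]")
})

test_that("overlap integrals: constant, sifting, and analytic Gaussian cases", {
  un <- normalize_to_unit_intensity(gaussian_spectrum(526, 25))
  expect_equal(unit_photoconversion_rate(function(w) rep(0.002, length(w)), un),
               0.002, tolerance = 1e-9)
  # near-delta spectrum sifts out sigma(lambda0)
  sig <- function(w) 0.01 * exp(-(w - 550)^2 / (2 * 40^2))
  sharp <- normalize_to_unit_intensity(gaussian_spectrum(600, 0.8))
  expect_equal(unit_photoconversion_rate(sig, sharp), sig(600), tolerance = 1e-3)
  # Gaussian x Gaussian closed-form product integral
  s1 <- 20; s2 <- 25 / (2 * sqrt(2 * log(2))); m1 <- 560; m2 <- 540
  amp <- 0.05
  sigg <- function(w) amp * exp(-(w - m1)^2 / (2 * s1^2))
  ung <- normalize_to_unit_intensity(gaussian_spectrum(m2, 25))
  analytic <- amp * s1 / sqrt(s1^2 + s2^2) * exp(-(m1 - m2)^2 / (2 * (s1^2 + s2^2)))
  expect_equal(unit_photoconversion_rate(sigg, ung), analytic, tolerance = 1e-4)
})

test_that("overlap rates are additive over spectral mixtures", {
  sig <- function(w) 0.01 * exp(-(w - 550)^2 / (2 * 50^2))
  ua <- normalize_to_unit_intensity(gaussian_spectrum(500, 30))
  ub <- normalize_to_unit_intensity(gaussian_spectrum(620, 30))
  for (w in c(0.2, 0.5, 0.9)) {
    mix <- ua
    mix$flux_density <- w * ua$flux_density + (1 - w) * ub$flux_density
    expect_equal(unit_photoconversion_rate(sig, mix),
                 w * unit_photoconversion_rate(sig, ua) +
                 (1 - w) * unit_photoconversion_rate(sig, ub),
                 tolerance = 1e-12)
  }
})

test_that("halving the wavelength step barely changes smooth overlap rates", {
  sig <- function(w) 0.01 * exp(-(w - 550)^2 / (2 * 50^2))
  k1 <- unit_photoconversion_rate(
    sig, normalize_to_unit_intensity(gaussian_spectrum(560, 40, grid = common_grid(by = 0.5))))
  k2 <- unit_photoconversion_rate(
    sig, normalize_to_unit_intensity(gaussian_spectrum(560, 40, grid = common_grid(by = 0.25))))
  expect_lt(abs(k1 - k2) / k1, 1e-4)
})

test_that("grayscale conversion: endpoints, midpoint rounding, exact round trip", {
  expect_identical(intensity_to_grayscale(20, 20), 4095L)
  expect_identical(intensity_to_grayscale(0, 20), 0L)
  expect_identical(intensity_to_grayscale(10, 20), 2048L)  # 2047.5 rounds away from zero
  expect_error(intensity_to_grayscale(21, 20, channel = "green"), "green")
  levels <- 0:4095
  back <- intensity_to_grayscale(grayscale_to_intensity(levels, 17.3), 17.3)
  expect_identical(back, levels)
})
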