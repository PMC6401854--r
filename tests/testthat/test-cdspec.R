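make_gauss_spectrum <- function(ph, centers = c(pos = 228, neg = 212),
                                amps = c(pos = 800, neg = -300),
                                lam = seq(200, 300, by = 0.5)) {
  th <- amps["pos"] * exp(-0.5 * ((lam - centers["pos"]) / 9)^2) +
    amps["neg"] * exp(-0.5 * ((lam - centers["neg"]) / 7)^2)
  cd_spectrum(lam, th, ph = ph, normalized = TRUE)
}

test_that("repeat-unit molar concentration follows from atomic masses", {
  # MBA 154.17 + residue mass, 0.5 mg/mL polymer solutions
  expect_equal(repeat_unit_concentration(0.5, 271.32) * 1000, 1.843,
               tolerance = 1e-3)  # valine polymer
  expect_equal(repeat_unit_concentration(0.5, 243.26) * 1000, 2.056,
               tolerance = 1e-3)  # alanine polymer
  masses <- vapply(c("M-l-Ala", "M-l-Val", "M-l-Leu"),
                   function(p) default_polymer(p)$repeat_unit_mass,
                   numeric(1))
  mean_mM <- mean(repeat_unit_concentration(0.5, masses)) * 1000
  expect_gt(mean_mM, 1.83 - 0.17)
  expect_lt(mean_mM, 1.83 + 0.17)
  expect_error(repeat_unit_concentration(-1, 100), "positive")
})

test_that("molar-ellipticity normalisation is a linear scaling", {
  lam <- seq(200, 300, by = 1)
  raw <- cd_spectrum(lam, rep(9.15, length(lam)), ph = 7,
                     repeat_unit_conc = 1.83e-3)
  norm <- to_molar_ellipticity(raw)
  expect_equal(norm$ellipticity, rep(5000, length(lam)), tolerance = 1e-9)
  expect_true(norm$normalized)
  # zero preservation
  zero <- to_molar_ellipticity(cd_spectrum(lam, rep(0, length(lam)), ph = 7,
                                           repeat_unit_conc = 1.83e-3))
  expect_true(all(zero$ellipticity == 0))
  # doubling the concentration halves theta everywhere
  half <- to_molar_ellipticity(cd_spectrum(lam, rep(9.15, length(lam)),
                                           ph = 7,
                                           repeat_unit_conc = 2 * 1.83e-3))
  expect_equal(half$ellipticity, norm$ellipticity / 2)
  # linearity: theta of a summed raw signal equals the sum of thetas
  set.seed(4)
  s1 <- rnorm(length(lam)); s2 <- rnorm(length(lam))
  th <- function(s) to_molar_ellipticity(
    cd_spectrum(lam, s, ph = 5, repeat_unit_conc = 1.9e-3))$ellipticity
  expect_equal(th(s1 + s2), th(s1) + th(s2), tolerance = 1e-12)
  # concentration derivable from mass concentration + repeat-unit mass
  viaMass <- to_molar_ellipticity(cd_spectrum(lam, rep(1, length(lam)),
                                              ph = 7, mass_conc = 0.5),
                                  repeat_unit_mass = 271.32)
  expect_equal(viaMass$repeat_unit_conc, 0.5 / 271.32)
  expect_error(to_molar_ellipticity(cd_spectrum(lam, rep(1, length(lam)),
                                                ph = 7)),
               "normalise")
})

test_that("differential series references the pH-3 spectrum", {
  s3 <- make_gauss_spectrum(3, amps = c(pos = 100, neg = 0))
  s9 <- make_gauss_spectrum(9, amps = c(pos = 600, neg = 0))
  ds <- differential_series(list(s3, s9), wavelength = 228)
  expect_equal(ds$delta_theta[ds$ph == 3], 0)
  expect_equal(ds$delta_theta[ds$ph == 9], 500, tolerance = 1e-9)
  # missing reference
  expect_error(differential_series(list(s9, make_gauss_spectrum(7))),
               "ref_ph")
  # raw spectra are rejected
  raw <- cd_spectrum(s3$wavelengths, s3$ellipticity, ph = 3)
  expect_error(differential_series(list(raw, s9)), "normalised")
})

test_that("peak finder agrees with exhaustive search and flags shapes", {
  s <- make_gauss_spectrum(9, centers = c(pos = 231, neg = 210))
  pk <- find_peaks(s, c(200, 280))
  oracle <- grid_extrema(s$wavelengths, s$ellipticity, c(200, 280))
  expect_equal(pk$lambda_max, oracle$lambda_max)
  expect_equal(pk$lambda_min, oracle$lambda_min)
  expect_equal(pk$lambda_max, 231, tolerance = 0.5)  # grid step
  expect_true(pk$min_below_max)
  expect_false(pk$degenerate)
  # flat spectrum is degenerate
  flat <- cd_spectrum(seq(200, 300, 1), rep(0, 101), ph = 5,
                      normalized = TRUE)
  expect_true(find_peaks(flat)$degenerate)
  expect_error(find_peaks(s, c(150, 280)), "range")
})

test_that("sigmoid fit recovers a noise-free logistic exactly", {
  ph <- seq(3, 11, by = 0.25)
  y <- logistic_reference(ph, lower = 0, upper = 1000, ph50 = 6.8, slope = 1)
  fit <- fit_sigmoid(data.frame(ph = ph, delta_theta = y))
  expect_equal(fit$inflection_ph, 6.8, tolerance = 1e-6)
  expect_equal(fit$lower_plateau, 0, tolerance = 1e-4)
  expect_equal(fit$upper_plateau, 1000, tolerance = 1e-4)
  expect_equal(fit$slope, 1, tolerance = 1e-5)
  expect_true(all(is.finite(fit$covariance)))
  # degenerate constant input
  expect_error(fit_sigmoid(data.frame(ph = ph, delta_theta = rep(5, length(ph)))),
               "zero-amplitude")
  expect_error(fit_sigmoid(data.frame(ph = 1:5, delta_theta = 1:5)),
               "at least 8")
})

test_that("sigmoid inflection is stable under 2% noise", {
  ph <- seq(3, 11, by = 0.25)
  truth <- logistic_reference(ph, 0, 1000, 7.3, 0.9)
  set.seed(20)
  errs <- vapply(1:20, function(i) {
    y <- truth + rnorm(length(ph), 0, 20)
    abs(fit_sigmoid(data.frame(ph = ph, delta_theta = y))$inflection_ph - 7.3)
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
})

test_that("plateaus bracket nearly all points at 2% noise", {
  ph <- seq(3, 11, by = 0.2)
  set.seed(7)
  y <- logistic_reference(ph, 100, 1100, 6.8, 1.2) + rnorm(length(ph), 0, 20)
  fit <- fit_sigmoid(data.frame(ph = ph, delta_theta = y))
  inside <- y >= fit$lower_plateau - 3 * 20 & y <= fit$upper_plateau + 3 * 20
  expect_gte(mean(inside), 0.95)
})

test_that("differential series of an amine-coupled generator is monotone and
           its sigmoid inflection equals the generating pKa2", {
  pol <- default_polymer("M-l-Leu")
  # pure proportional coupling (positive band only): the differential is an
  # exact base-10 logistic with ph50 = pKa2 and slope = 1/beta2
  raw <- simulate_cd_series(pol, cd_series_params(noise_sd = 0, seed = 1,
                                                  neg_amplitude = 0))
  norm <- lapply(raw, to_molar_ellipticity, pol$repeat_unit_mass)
  ds <- differential_series(norm, ref_ph = 3, wavelength = 228)
  expect_true(all(diff(ds$delta_theta) > -1e-9))
  fit <- fit_sigmoid(ds)
  expect_equal(fit$inflection_ph, pol$base_group$pka, tolerance = 1e-6)
  expect_equal(fit$slope, 1 / pol$base_group$beta, tolerance = 1e-4)
  # with the blue-shifting negative band included the inflection moves by
  # far less than the 0.05 pH reading precision
  raw2 <- simulate_cd_series(pol, cd_series_params(noise_sd = 0, seed = 1))
  norm2 <- lapply(raw2, to_molar_ellipticity, pol$repeat_unit_mass)
  fit2 <- fit_sigmoid(differential_series(norm2, wavelength = 231))
  expect_equal(fit2$inflection_ph, pol$base_group$pka, tolerance = 0.05 / 7.3)
})
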