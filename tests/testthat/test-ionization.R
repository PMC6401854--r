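test_that("apparent pKa inverts the Henderson-Hasselbalch relation", {
  # at half-ionization the log term vanishes
  expect_identical(apparent_pka(0.5, 6.8), 6.8)
  # analytic: log10(1/9) = -0.954...
  expect_equal(apparent_pka(0.9, 4.954), 4.954 + log10(1 / 9))
  expect_equal(apparent_pka(0.9, 4.954), 4.000, tolerance = 1e-3)
  # symmetry about alpha = 0.5
  expect_equal(apparent_pka(0.1, 3.046), 4.000, tolerance = 1e-3)
  # round trip for a sweep of alphas: pH generated from the relation
  # returns the generating pKa
  for (pka in c(2.3, 7.5, 10.1)) {
    a <- seq(0.01, 0.99, by = 0.014)
    ph <- pka - log10((1 - a) / a)
    expect_equal(apparent_pka(a, ph), rep(pka, length(a)), tolerance = 1e-12)
  }
  expect_error(apparent_pka(0, 4), "alpha")
  expect_error(apparent_pka(1, 4), "alpha")
})

test_that("Katchalsky-Spitnik regression recovers pKa and beta", {
  a <- seq(0.2, 0.8, length.out = 30)
  # noise-free modified Henderson-Hasselbalch data
  cases <- list(c(7.3, 1.5), c(6.8, 1.2), c(2.3, 0.8))
  for (cs in cases) {
    ph <- cs[1] - cs[2] * log10((1 - a) / a)
    fit <- fit_katchalsky_spitnik(data.frame(alpha = a, ph = ph))
    expect_equal(fit$pka, cs[1], tolerance = 1e-6)
    expect_equal(fit$beta, cs[2], tolerance = 1e-6)
    expect_gt(fit$r_squared, 1 - 1e-9)
  }
  # beta = 1 reduces to the plain relation: slope of pH on x is exactly -1
  ph1 <- 5 - log10((1 - a) / a)
  fit1 <- fit_katchalsky_spitnik(data.frame(alpha = a, ph = ph1))
  expect_equal(fit1$beta, 1, tolerance = 1e-9)
  # points outside the alpha window are excluded
  aa <- c(0.05, 0.1, a, 0.9, 0.95)
  pha <- 6 - 1.3 * log10((1 - aa) / aa) + c(rep(2, 2), rep(0, 30), rep(-2, 2))
  fitw <- fit_katchalsky_spitnik(data.frame(alpha = aa, ph = pha))
  expect_equal(fitw$n_points, 30)
  expect_equal(fitw$beta, 1.3, tolerance = 1e-6)
  expect_error(
    fit_katchalsky_spitnik(data.frame(alpha = c(0.3, 0.4, 0.5), ph = 1:3)),
    "insufficient")
})

test_that("Katchalsky-Spitnik fit tolerates measurement noise", {
  set.seed(11)
  a <- seq(0.2, 0.8, length.out = 30)
  errs <- replicate(25, {
    ph <- 6.8 - 1.2 * log10((1 - a) / a) + rnorm(30, 0, 0.02)
    fit <- fit_katchalsky_spitnik(data.frame(alpha = a, ph = ph))
    c(abs(fit$pka - 6.8), abs(fit$beta - 1.2))
  })
  expect_lt(mean(errs[1, ]), 0.05)
  expect_lt(mean(errs[2, ]), 0.1)
})

test_that("speciation fractions are normalised product microstates", {
  spec <- polymer_spec("toy", 250,
                       ionizable_group("carboxyl-acid", 2.5, 1),
                       ionizable_group("amine-base", 7.5, 1.3))
  # analytic single points
  expect_equal(fraction_protonated_base(7.5, spec$base_group), 0.5)
  expect_equal(fraction_deprotonated_acid(3.5, spec$acid_group),
               1 / (1 + 10^-1))
  # product rule at f_coo = 0.909..., f_nh = 0.8
  ph_nh08 <- 7.5 + 1.3 * log10(4)   # f_nh = 0.8 there
  spec2 <- polymer_spec("toy2", 250,
                        ionizable_group("carboxyl-acid", 2.5, 1),
                        ionizable_group("amine-base", 7.5, 1.3))
  f_coo <- 1 / (1 + 10^((2.5 - 3.5) / 1))
  sp <- speciation(spec2, ph_grid = 3.5)
  expect_equal(sp$f_coo, f_coo)
  # frozen product-rule fractions for f_coo = 0.909, f_nh = 0.8
  f1 <- 0.909; f2 <- 0.8
  expect_equal(c((1 - f1) * f2, f1 * f2, (1 - f1) * (1 - f2), f1 * (1 - f2)),
               c(0.0728, 0.7272, 0.0182, 0.1818))
  # grid-wide invariants
  sp <- speciation(spec, ph_grid = seq(0, 14, by = 0.05))
  sums <- sp$f_cation + sp$f_zwitterion + sp$f_neutral + sp$f_anion
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(sp[c("f_cation", "f_zwitterion", "f_neutral",
                       "f_anion")] >= 0))
  expect_true(all(diff(sp$net_charge) <= 1e-12))
  expect_equal(sp$net_charge, sp$f_nh - sp$f_coo)
  # half-ionization invariance: f_nh = 0.5 at pH = pKa2 for any beta2
  for (b2 in c(0.5, 1, 1.35, 2.2)) {
    g <- ionizable_group("amine-base", 7.1, b2)
    expect_equal(fraction_protonated_base(7.1, g), 0.5)
  }
})

test_that("isoelectric point matches analytic and grid oracles", {
  mk <- function(pka1, b1, pka2, b2)
    polymer_spec("x", 100, ionizable_group("carboxyl-acid", pka1, b1),
                 ionizable_group("amine-base", pka2, b2))
  # symmetric case: midpoint
  expect_equal(isoelectric_point(mk(3, 1, 7, 1)), 5, tolerance = 1e-6)
  # asymmetric betas: brute-force grid minimiser of |net charge|
  expect_equal(isoelectric_point(mk(2, 1.4, 9, 0.8)),
               grid_isoelectric(2, 1.4, 9, 0.8), tolerance = 1e-4)
  expect_equal(isoelectric_point(mk(2.3, 0.8, 8.1, 1.35)),
               grid_isoelectric(2.3, 0.8, 8.1, 1.35), tolerance = 1e-4)
})

test_that("type constructors enforce their invariants", {
  expect_error(ionizable_group("amine-base", pka = 15), "pka")
  expect_error(ionizable_group("amine-base", pka = 7, beta = 0), "beta")
  expect_error(
    polymer_spec("bad", 100, ionizable_group("carboxyl-acid", 8),
                 ionizable_group("amine-base", 3)),
    "pKa1")
  expect_error(titration_curve(c(1, 0.5), c(3, 4), 0.1,
                               n_repeat_units = 1e-3),
               "monotone")
  expect_error(titration_curve(c(0, 1), c(3, 15), 0.1,
                               n_repeat_units = 1e-3),
               "pH")
})

test_that("alpha extraction inverts the titration simulator", {
  spec <- polymer_spec("toy", 250,
                       ionizable_group("carboxyl-acid", 2.3, 1),
                       ionizable_group("amine-base", 7.5, 1))
  curve <- simulate_titration(spec, titration_protocol(sample_conc = 0.05,
                                                       ph_noise_sd = 0))
  a <- compute_alpha(curve, spec)
  expect_s3_class(a$carboxyl, "alpha_series")
  expect_equal(half_neutralization_ph(a$carboxyl), 2.3, tolerance = 0.05)
  expect_equal(half_neutralization_ph(a$amine), 7.5, tolerance = 0.05)
  # alphas are clamped inside (0, 1) and monotone in pH (noise-free)
  for (s in a) {
    expect_true(all(s$alpha > 0 & s$alpha < 1))
    expect_true(all(diff(s$alpha[order(s$ph)]) > -1e-9))
  }
  # zero polymer: empty series with a warning
  blank <- simulate_titration(NULL, titration_protocol(sample_conc = 0,
                                                       ph_noise_sd = 0))
  expect_warning(empty <- compute_alpha(blank, spec), "empty")
  expect_equal(nrow(empty$carboxyl), 0)
  expect_equal(nrow(empty$amine), 0)
})
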