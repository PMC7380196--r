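# Nonlinear estimation: identifiability on noiseless data, degenerate-input
# flagging, uncertainty machinery.

test_that("inversion-recovery fit recovers noiseless and noisy rates", {
  tr <- study_truth(r1 = list(apo = c(active = 2, inactive = 2),
                              ligand = c(active = 2, inactive = 2)))
  s0 <- generate_inversion_recovery(tr, "active", "apo", seed = 1,
                                    noise_sigma = 0)
  f0 <- fit_inversion_recovery(s0)
  expect_true(f0$converged)
  expect_equal(f0$r1, 2, tolerance = 1e-6)
  # 1% noise, 10 delays: within 5%
  errs <- vapply(1:10, function(s) {
    f <- fit_inversion_recovery(
      generate_inversion_recovery(tr, "active", "apo", seed = 100 + s))
    abs(f$r1 - 2) / 2
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("constant inversion-recovery intensities are flagged", {
  s <- relaxation_series(seq(0.025, 0.8, length.out = 10), rep(0.8, 10))
  f <- fit_inversion_recovery(s)
  expect_false(f$converged)
  expect_true(any(grepl("unidentifiable", f$flags)))
})

test_that("Luz-Meiboom fit recovers the rate on fast-exchange data", {
  # fast limit: k_app should equal the generating k_i within 2%
  tt <- 0.00384
  nu <- (1:46)[c(1, 2, 4, 6, 9, 13, 18, 24, 30, 36, 41, 46)] / (2 * tt)
  dw <- delta_omega_from_ppm(0.5, 564)
  k <- 25 * dw
  r2 <- carver_richards_r2(nu, two_state_fast_params(k, 0.25, 0.5, 20), dw)
  d <- cpmg_dataset(nu, exp(-tt * r2), 564, tt)
  f <- fit_luz_meiboom(d)
  expect_true(f$converged)
  expect_lt(abs(f$params$k_app - k) / k, 0.02)
  expect_equal(f$params$c, 0.25 * 0.75 * dw^2, tolerance = 0.05)
})

test_that("flat dispersion pins c at zero and flags unidentifiability", {
  tt <- 0.00384
  nu <- (1:14) / (2 * tt)
  d <- cpmg_dataset(nu, rep(exp(-tt * 30), 14), 564, tt)
  f <- fit_luz_meiboom(d)
  expect_equal(f$params$c, 0)
  expect_equal(f$params$r2_0, 30, tolerance = 1e-6)
  expect_true(any(grepl("unidentifiable", f$flags)))
})

test_that("replicate datasets give consistent Luz-Meiboom estimates", {
  tr <- study_truth()
  f1 <- fit_luz_meiboom(generate_cpmg_series(tr, "active", "apo", 659, seed = 11))
  f2 <- fit_luz_meiboom(generate_cpmg_series(tr, "active", "apo", 659, seed = 12))
  joint <- sqrt(f1$se[["k_app"]]^2 + f2$se[["k_app"]]^2)
  expect_lt(abs(f1$params$k_app - f2$params$k_app), 3 * joint)
})

test_that("global Carver-Richards fit is exact on model-matched noiseless data", {
  tr <- study_truth()
  ds <- list()
  for (cond in c("apo", "ligand")) for (f in c(564, 659))
    ds[[length(ds) + 1]] <- generate_cpmg_series(tr, "active", cond, f,
                                                 seed = 1, noise_sigma = 0,
                                                 r2_method = "closed_form")
  g <- fit_carver_richards_global(ds)
  expect_true(g$converged)
  expect_equal(g$delta_delta, 1.2, tolerance = 1e-3)
  expect_equal(unname(g$k_i[["apo"]]), 4300, tolerance = 1e-3)
  expect_equal(unname(g$k_i[["ligand"]]), 7300, tolerance = 1e-3)
  expect_equal(unname(g$p_minor[["apo"]]), 0.19, tolerance = 1e-3)
  expect_equal(unname(g$p_minor[["ligand"]]), 0.30, tolerance = 1e-3)
  expect_equal(g$r2_0, c(30, 45, 30, 45), tolerance = 1e-3)
  # sanity bound: the fitted objective cannot exceed the objective at truth
  expect_lte(g$deviance, 1e-8)
})

test_that("global fit flags unidentifiable exchange when ddelta = 0", {
  tr <- study_truth(fast = list(
    active = list(apo = list(k_i = 4300, p_extended = 0.81, p_compact = 0.19,
                             delta_delta = 0, minor = "compact")),
    inactive = list(apo = list(k_i = 8000, p_extended = 0.009,
                               p_compact = 0.991, delta_delta = 2.9,
                               minor = "extended"))),
    slow = list(apo = list(k_mn = 1.08, k_nm = 1.23)))
  ds <- lapply(c(564, 659), function(f)
    generate_cpmg_series(tr, "active", "apo", f, seed = 2, noise_sigma = 0))
  g <- fit_carver_richards_global(ds)
  expect_true(any(grepl("unidentifiable", g$flags)))
})

test_that("single-field global fit degrades with a recorded warning flag", {
  tr <- study_truth()
  ds <- list(generate_cpmg_series(tr, "active", "apo", 564, seed = 3))
  g <- fit_carver_richards_global(ds)
  expect_true(any(grepl("single-field", g$flags)))
})

test_that("fast-regime consistency: k_app matches the global-fit k_i", {
  tt <- 0.00384
  echoes <- c(1, 2, 4, 6, 9, 13, 18, 24, 30, 36, 41, 46)
  nu <- echoes / (2 * tt)
  dd <- 0.4
  k <- 25 * delta_omega_from_ppm(dd, 659)
  ds <- lapply(c(564, 659), function(f) {
    dw <- delta_omega_from_ppm(dd, f)
    r2 <- carver_richards_r2(nu, two_state_fast_params(k, 0.3, dd, 22), dw)
    cpmg_dataset(nu, exp(-tt * r2), f, tt)
  })
  g <- fit_carver_richards_global(ds)
  lm <- fit_luz_meiboom(ds[[2]])
  # in the fast limit both describe the same apparent rate
  expect_lt(abs(lm$params$k_app - g$k_i[[1]]) / g$k_i[[1]], 0.05)
})

test_that("saturation-transfer fit recovers rates and flags degenerate traces", {
  taus <- exp(seq(log(0.025), log(1), length.out = 8))
  s <- saturation_series(taus, slow_exchange_intensity(taus, 1, 1.08, 1.5),
                         observed = "inactive", saturated = "active",
                         r1 = 1.5, r1_provenance = "user")
  f <- fit_saturation_transfer(s)
  expect_true(f$converged)
  expect_equal(f$k, 1.08, tolerance = 1e-6)
  expect_equal(f$i0, 1, tolerance = 1e-6)
  # flat trace
  s0 <- saturation_series(taus, rep(1, 8), "inactive", "active",
                          r1 = 1.5, r1_provenance = "user")
  f0 <- fit_saturation_transfer(s0)
  expect_true(any(grepl("k ~ 0", f0$flags)))
  # missing R1 is a precondition error
  s_na <- saturation_series(taus, rep(1, 8), "inactive", "active")
  expect_error(fit_saturation_transfer(s_na), "r1")
})

test_that("covariance uncertainties match the closed-form linear model", {
  withr::with_seed(8, {
    x <- seq(0, 10, length.out = 25)
    y <- 2 + 0.7 * x + rnorm(25, 0, 0.3)
  })
  fit <- fluorex:::.ls_fit(c(0, 0), function(p) p[1] + p[2] * x, y)
  lmfit <- lm(y ~ x)
  expect_equal(fit$par, unname(coef(lmfit)), tolerance = 1e-6)
  expect_equal(fit$se, unname(summary(lmfit)$coefficients[, 2]),
               tolerance = 1e-4)
})

test_that("bootstrap uncertainties are seed-deterministic and sensible", {
  tr <- study_truth()
  s <- generate_saturation_series(tr, "inactive", "ligand", seed = 31)
  f <- fit_saturation_transfer(s)
  u1 <- estimate_uncertainties(f, n_boot = 50, seed = 99)
  u2 <- estimate_uncertainties(f, n_boot = 50, seed = 99)
  expect_identical(u1, u2)
  # covariance and bootstrap agree in order of magnitude
  expect_lt(u1$bootstrap_se[2], 10 * u1$covariance_se[2])
  expect_gt(u1$bootstrap_se[2], 0.1 * u1$covariance_se[2])
  # noiseless exact fit: covariance uncertainties ~ 0
  taus <- exp(seq(log(0.025), log(1), length.out = 8))
  s0 <- saturation_series(taus, slow_exchange_intensity(taus, 1, 4.2, 1.5),
                          "inactive", "active", r1 = 1.5,
                          r1_provenance = "user")
  f0 <- fit_saturation_transfer(s0)
  expect_lt(max(estimate_uncertainties(f0, "covariance")$covariance_se), 1e-4)
})

test_that("reciprocal saturation fits satisfy detailed balance with integrals", {
  tr <- study_truth()
  f_ia <- fit_saturation_transfer(
    generate_saturation_series(tr, "inactive", "apo", seed = 41))
  f_ai <- fit_saturation_transfer(
    generate_saturation_series(tr, "active", "apo", seed = 42))
  th <- derive_slow_exchange_thermo(f_ia$k, f_ai$k)
  # populations from a noiseless simulated spectrum of the same equilibrium
  sl <- tr$slow$apo
  sys <- two_site_system(delta_omega_from_ppm(-82.7, 564),
                         delta_omega_from_ppm(-84.1, 564),
                         p_a = sl$k_mn / (sl$k_mn + sl$k_nm),
                         k_ex = sl$k_mn + sl$k_nm, r2_a = 120, r2_b = 80)
  sp <- simulate_spectrum(sys, seq(-88, -79, by = 0.002), 564)
  pops <- populations_from_integrals(peak_integral(sp, c(-83.4, -79.5)),
                                     peak_integral(sp, c(-87.5, -83.4)))
  se <- sqrt(f_ia$se^2 + f_ai$se^2) / (f_ia$k + f_ai$k)  # rough population se
  expect_lt(abs(th$p_active - pops[[1]]), 3 * se + 0.02)
})
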