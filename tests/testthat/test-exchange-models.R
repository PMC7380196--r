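# Closed-form exchange models: values frozen from independent
# arbitrary-precision evaluation (mpmath, 30 significant digits).

test_that("effective rate from constant-time intensities matches the closed form", {
  expect_equal(r2_effective(1, 1, 0.00384), 0)
  expect_equal(r2_effective(exp(-1), 1, 0.00384), 1 / 0.00384)
  expect_equal(r2_effective(0.7, 1, 0.00384), 92.8840999840449, tolerance = 1e-12)
  # vectorised, and negative rates allowed when I > I0
  expect_lt(r2_effective(1.05, 1, 0.00384), 0)
  expect_length(r2_effective(c(0.5, 0.9), 1, 0.00384), 2)
})

test_that("effective rate rejects non-positive inputs", {
  expect_error(r2_effective(0, 1, 0.00384), "positive")
  expect_error(r2_effective(-0.1, 1, 0.00384), "positive")
  expect_error(r2_effective(0.5, 0, 0.00384), "positive")
  expect_error(r2_effective(0.5, 1, 0), "positive")
})

test_that("Luz-Meiboom dispersion has the right limits and frozen value", {
  p <- luz_meiboom_params(k_app = 1000, c = 2e5, r2_0 = 20)
  expect_equal(luz_meiboom_r2(500, p), 35.1531370959961, tolerance = 1e-12)
  # no exchange contribution
  expect_equal(luz_meiboom_r2(123, luz_meiboom_params(5e3, 0, 20)), 20)
  # fast-pulsing limit quenches all exchange
  expect_equal(luz_meiboom_r2(1e9, p), 20, tolerance = 1e-6)
  expect_error(luz_meiboom_r2(500, list(k_app = 0, c = 1e4, r2_0 = 20)),
               "k_app")
})

test_that("Luz-Meiboom curve is non-increasing in nu for random parameters", {
  withr::with_seed(11, {
    for (i in 1:50) {
      p <- luz_meiboom_params(k_app = 10^runif(1, 2, 4),
                              c = 10^runif(1, 3, 6),
                              r2_0 = runif(1, 5, 60))
      nu <- sort(10^runif(30, 1.5, 4))
      r2 <- luz_meiboom_r2(nu, p)
      expect_true(all(diff(r2) <= 1e-9))
      expect_true(all(r2 >= p$r2_0 - 1e-9))
    }
  })
})

test_that("Carver-Richards reduces correctly in degenerate limits", {
  nu <- c(130.2083, 520.8333, 2083.333, 5989.583)
  # single-state limit
  p0 <- two_state_fast_params(k_i = 3000, p_b = 0, delta_delta = 2, r2_0 = 25)
  expect_equal(carver_richards_r2(nu, p0, delta_omega_from_ppm(2, 564)),
               rep(25, 4), tolerance = 1e-9)
  # degenerate shifts
  p1 <- two_state_fast_params(k_i = 3000, p_b = 0.2, delta_delta = 0, r2_0 = 25)
  expect_equal(carver_richards_r2(nu, p1, 0), rep(25, 4), tolerance = 1e-9)
  # no exchange at all (psi^2 + xi^2 = 0)
  p2 <- two_state_fast_params(k_i = 0, p_b = 0.2, delta_delta = 0, r2_0 = 25)
  expect_equal(carver_richards_r2(nu, p2, 0), rep(25, 4))
})

test_that("Carver-Richards is invariant under swapping the populations", {
  nu <- seq(130, 6000, length.out = 20)
  dw <- delta_omega_from_ppm(1.7, 659)
  for (pb in c(0.009, 0.19, 0.4)) {
    a <- carver_richards_r2(nu, two_state_fast_params(5200, pb, 1.7, 31), dw)
    b <- carver_richards_r2(nu, two_state_fast_params(5200, 1 - pb, 1.7, 31), dw)
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("Carver-Richards approaches R2,0 at fast pulsing", {
  p <- two_state_fast_params(4300, 0.19, 1.2, 30)
  dw <- delta_omega_from_ppm(1.2, 564)
  expect_equal(carver_richards_r2(1e7, p, dw), 30, tolerance = 1e-3)
})

test_that("Carver-Richards agrees with Luz-Meiboom in the fast-exchange limit", {
  # k_i >> domega: composite c = pA pB domega^2, k_app = k_i
  nu <- (1:46) / (2 * 0.00384)
  for (field in c(564, 659)) {
    for (pb in c(0.1, 0.3, 0.5)) {
      dd <- 0.5
      dw <- delta_omega_from_ppm(dd, field)
      k <- 25 * dw
      cr <- carver_richards_r2(nu, two_state_fast_params(k, pb, dd, 20), dw)
      lm <- luz_meiboom_r2(nu, luz_meiboom_params(k, pb * (1 - pb) * dw^2, 20))
      expect_lt(max(abs(cr - lm) / lm), 0.01)
    }
  }
})

test_that("slow-exchange intensity follows the Forsen-Hoffman closed form", {
  expect_equal(slow_exchange_intensity(0, 2.5, 3.1, 0.9), 2.5)
  # steady-state ratio R1/(k+R1) = 1/2 when k = R1
  expect_equal(slow_exchange_intensity(1e6, 1, 1.3, 1.3), 0.5)
  expect_equal(slow_exchange_intensity(0.5, 1, 1.2, 1.0), 0.636111500198952,
               tolerance = 1e-12)
  # degenerate: no decay channels at all
  expect_equal(slow_exchange_intensity(c(0, 1, 5), 1, 0, 0), rep(1, 3))
})

test_that("slow-exchange intensity decays strictly and stays above its plateau", {
  tau <- seq(0, 3, by = 0.05)
  for (k in c(0.5, 1.2, 8.3)) {
    y <- slow_exchange_intensity(tau, 1, k, 1.5)
    expect_true(all(diff(y) < 0))
    expect_true(all(y >= 1.5 / (k + 1.5) - 1e-12))
  }
})

test_that("slow-exchange thermodynamics reproduce the reference rate table", {
  th <- derive_slow_exchange_thermo(1.08, 1.23, 298.15)
  expect_equal(th$k_s, 2.31)
  expect_equal(round(th$p_active, 2), 0.47)
  expect_equal(round(th$p_inactive, 2), 0.53)
  # detailed balance holds exactly by construction
  expect_equal(th$p_active * th$k_nm, th$p_inactive * th$k_mn)
  # frozen high-precision evaluation for the ligand-bound rates
  th2 <- derive_slow_exchange_thermo(4.2, 8.3, 298.15)
  expect_equal(th2$delta_g$active_minus_inactive, 0.403582694576040,
               tolerance = 1e-12)
  expect_equal(th2$p_active, 0.336)
})

test_that("free-energy difference is antisymmetric and vanishes at symmetry", {
  th <- derive_slow_exchange_thermo(2.7, 2.7)
  expect_equal(th$p_active, 0.5)
  expect_equal(th$delta_g$active_minus_inactive, 0)
  th2 <- derive_slow_exchange_thermo(1.9, 6.4)
  expect_equal(th2$delta_g$active_minus_inactive,
               -th2$delta_g$inactive_minus_active)
  rev <- derive_slow_exchange_thermo(6.4, 1.9)
  expect_equal(rev$delta_g$active_minus_inactive,
               th2$delta_g$inactive_minus_active)
  expect_error(derive_slow_exchange_thermo(0, 1), "positive")
})

test_that("ppm/angular-frequency conversion is exact and invertible", {
  expect_equal(delta_omega_from_ppm(0, 564), 0)
  expect_equal(delta_omega_from_ppm(1.2, 564), 2 * pi * 676.8)
  expect_equal(delta_omega_from_ppm(2.9, 659), 12007.7954405509,
               tolerance = 1e-12)
  expect_equal(ppm_from_delta_omega(delta_omega_from_ppm(2.9, 659), 659), 2.9)
})
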