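#' Gas constant in kcal mol^-1 K^-1
#'
#' Value used throughout for free-energy calculations.
#' @export
gas_constant_kcal <- 1.9872e-3

#' Effective transverse relaxation rate from constant-time CPMG intensities
#'
#' Converts the peak intensity measured after a constant-time CPMG element of
#' duration `constant_time` into an effective transverse relaxation rate,
#' relative to the reference intensity acquired without the relaxation block:
#' \deqn{R_{2,eff} = -T_{CPMG}^{-1} \ln(I/I_0)}
#'
#' @param intensity Peak intensity `I(nu_cpmg)` (arbitrary units, > 0).
#'   May be a vector.
#' @param reference_intensity Reference intensity `I_0` (> 0).
#' @param constant_time Constant-time relaxation delay `T_CPMG` in seconds (> 0).
#' @return Effective relaxation rate(s) in s^-1. Negative values are possible
#'   when noise pushes `I` above `I_0`.
#' @examples
#' r2_effective(exp(-1), 1, 0.00384)  # 1/0.00384 = 260.42 s^-1
#' @export
r2_effective <- function(intensity, reference_intensity, constant_time) {
  if (!is.numeric(constant_time) || length(constant_time) != 1L || constant_time <= 0)
    stop("`constant_time` must be a single positive number", call. = FALSE)
  if (!is.numeric(reference_intensity) || any(reference_intensity <= 0))
    stop("`reference_intensity` must be positive", call. = FALSE)
  if (!is.numeric(intensity) || any(!is.finite(intensity)) || any(intensity <= 0))
    stop("`intensity` must be finite and positive (log of a non-positive ratio is undefined)",
         call. = FALSE)
  -log(intensity / reference_intensity) / constant_time
}

#' Parameters of the Luz-Meiboom fast-exchange dispersion model
#'
#' Container for the fast-limit model in which populations and shift
#' difference enter only through the composite `c = p_A p_B domega^2`.
#'
#' @param k_app Apparent exchange rate (s^-1, >= 0).
#' @param c Composite amplitude `p_A p_B domega^2` (s^-2, >= 0).
#' @param r2_0 Intrinsic transverse relaxation rate (s^-1, >= 0).
#' @return An object of class `luz_meiboom_params`.
#' @export
luz_meiboom_params <- function(k_app, c, r2_0) {
  stopifnot(is.numeric(k_app), is.numeric(c), is.numeric(r2_0),
            k_app >= 0, c >= 0, r2_0 >= 0)
  structure(list(k_app = k_app, c = c, r2_0 = r2_0),
            class = "luz_meiboom_params")
}

#' Luz-Meiboom dispersion curve
#'
#' Fast-exchange two-state relaxation dispersion:
#' \deqn{R_{2,eff}(\nu) = \frac{c}{k_{app}}\left[1 -
#'   \frac{4\nu}{k_{app}} \tanh\frac{k_{app}}{4\nu}\right] + R_{2,0}}
#'
#' @param nu_cpmg CPMG refocusing frequency (s^-1, > 0); may be a vector.
#' @param params A [luz_meiboom_params()] object (or a list with elements
#'   `k_app`, `c`, `r2_0`).
#' @return `R_2,eff` in s^-1; equals `r2_0` exactly when `c = 0` and
#'   decreases monotonically towards `r2_0` as `nu_cpmg` grows.
#' @export
luz_meiboom_r2 <- function(nu_cpmg, params) {
  stopifnot(is.numeric(nu_cpmg), all(nu_cpmg > 0))
  k <- params$k_app; cc <- params$c; r20 <- params$r2_0
  if (cc == 0) return(rep(r20, length(nu_cpmg)))
  if (k == 0) stop("`k_app` = 0 with non-zero exchange amplitude `c` is undefined",
                   call. = FALSE)
  x <- k / (4 * nu_cpmg)
  (cc / k) * (1 - tanh(x) / x) + r20
}

#' Parameters of the Carver-Richards two-state dispersion model
#'
#' @param k_i Exchange rate `k_i = k_AB + k_BA` (s^-1, >= 0).
#' @param p_b Population of state B (the convention here is `p_b <= 0.5`, the
#'   minor state, but any value in `[0, 1]` is accepted; the model is
#'   symmetric under swapping A and B).
#' @param delta_delta Chemical-shift difference magnitude `|ddelta|` in ppm
#'   (>= 0).
#' @param r2_0 Intrinsic transverse relaxation rate (s^-1); may be a named
#'   vector when one parameter set serves several datasets.
#' @return An object of class `two_state_fast_params`.
#' @export
two_state_fast_params <- function(k_i, p_b, delta_delta, r2_0) {
  stopifnot(is.numeric(k_i), k_i >= 0,
            is.numeric(p_b), p_b >= 0, p_b <= 1,
            is.numeric(delta_delta), delta_delta >= 0,
            is.numeric(r2_0), all(r2_0 >= 0))
  structure(list(k_i = k_i, p_a = 1 - p_b, p_b = p_b,
                 delta_delta = delta_delta, r2_0 = r2_0),
            class = "two_state_fast_params")
}

# Flat-argument Carver-Richards kernel, vectorised over nu.
.cr_r2 <- function(nu, k_i, p_b, delta_omega, r2_0, clamp_tol = 1e-9) {
  p_a <- 1 - p_b
  psi <- (p_b - p_a)^2 * k_i^2 - delta_omega^2 + 4 * p_b * p_a * k_i^2
  xi <- 2 * delta_omega * (p_b - p_a) * k_i
  root <- sqrt(psi^2 + xi^2)
  if (root == 0) return(rep(r2_0, length(nu)))  # no-exchange limit
  eta_p <- sqrt(pmax(root + psi, 0)) / (sqrt(8) * nu)
  eta_m <- sqrt(pmax(root - psi, 0)) / (sqrt(8) * nu)
  d_p <- 0.5 * ( 1 + (psi + 2 * delta_omega^2) / root)
  d_m <- 0.5 * (-1 + (psi + 2 * delta_omega^2) / root)
  arg <- d_p * cosh(eta_p) - d_m * cos(eta_m)
  bad <- arg < 1 - clamp_tol
  if (any(bad))
    stop(sprintf("arcosh argument %.6g < 1 beyond numerical tolerance at nu = %g",
                 min(arg), nu[which(bad)[1]]), call. = FALSE)
  arg <- pmax(arg, 1)
  r2_0 + 0.5 * (k_i - 2 * nu * acosh(arg))
}

#' Carver-Richards dispersion curve
#'
#' Closed-form effective transverse relaxation rate for two-site chemical
#' exchange, valid from slow through fast exchange:
#' \deqn{R_{2,eff} = R_{2,0} + \tfrac12\left(k_i - 2\nu_{CPMG}\,
#'   \mathrm{arcosh}(D_+\cosh\eta_+ - D_-\cos\eta_-)\right)}
#' with \eqn{\psi = (p_B-p_A)^2 k_i^2 - \Delta\omega^2 + 4 p_A p_B k_i^2},
#' \eqn{\xi = 2\Delta\omega (p_B-p_A) k_i},
#' \eqn{\eta_\pm = (\sqrt{8}\,\nu_{CPMG})^{-1}\sqrt{\pm\psi +
#'   \sqrt{\psi^2+\xi^2}}} and
#' \eqn{D_\pm = \tfrac12[\pm 1 + (\psi + 2\Delta\omega^2)/\sqrt{\psi^2+\xi^2}]}.
#'
#' The expression is invariant under swapping the two populations and
#' approaches `r2_0` as `nu_cpmg` grows. Floating-point arcosh arguments
#' within `1e-9` below 1 are clamped to 1; larger violations raise an error.
#'
#' @param nu_cpmg CPMG refocusing frequency (s^-1, > 0); may be a vector.
#' @param params A [two_state_fast_params()] object (or list with `k_i`,
#'   `p_b`, `r2_0`).
#' @param delta_omega Angular chemical-shift difference (rad s^-1); computed
#'   per dataset from `|ddelta|` and the field via [delta_omega_from_ppm()].
#' @return `R_2,eff` in s^-1.
#' @export
carver_richards_r2 <- function(nu_cpmg, params, delta_omega) {
  stopifnot(is.numeric(nu_cpmg), all(nu_cpmg > 0),
            params$p_b >= 0, params$p_b <= 1)
  r2_0 <- params$r2_0
  if (length(r2_0) != 1L)
    stop("`params$r2_0` must be a single rate here; per-dataset rates are handled by the fitter",
         call. = FALSE)
  .cr_r2(nu_cpmg, params$k_i, params$p_b, delta_omega, r2_0)
}

#' Residual intensity under saturation transfer (slow two-state exchange)
#'
#' Forsen-Hoffman decay of the observed resonance `m` while its exchange
#' partner is saturated:
#' \deqn{I_m(\tau) = \frac{I_m(0)}{k_{mn}+R_{1,m}}\left[k_{mn}
#'   e^{-\tau (k_{mn}+R_{1,m})} + R_{1,m}\right]}
#'
#' @param tau Saturation time(s) in seconds (>= 0).
#' @param i0 Intensity at `tau = 0` (> 0).
#' @param k_mn Exchange rate out of the observed state (s^-1, >= 0).
#' @param r1_m Longitudinal relaxation rate of the observed state (s^-1, >= 0).
#' @return Intensities; equal `i0` at `tau = 0`, decay monotonically to the
#'   plateau `i0 * r1_m / (k_mn + r1_m)`. When `k_mn + r1_m = 0` the trace is
#'   constant at `i0` (degenerate case).
#' @export
slow_exchange_intensity <- function(tau, i0, k_mn, r1_m) {
  stopifnot(is.numeric(tau), all(tau >= 0), i0 > 0, k_mn >= 0, r1_m >= 0)
  ktot <- k_mn + r1_m
  if (ktot == 0) return(rep(i0, length(tau)))
  (i0 / ktot) * (k_mn * exp(-tau * ktot) + r1_m)
}

#' Slow-exchange rates, populations and free-energy differences
#'
#' From the two directed fold-switch rates the total slow exchange rate,
#' the state populations and the free-energy difference follow as
#' \eqn{k_s = k_{mn} + k_{nm}}, \eqn{p_n = k_{mn}/k_s} and
#' \eqn{\Delta G_{nm} = -RT \ln(p_n/p_m)}. Directions are tagged explicitly:
#' `m` is the inactive and `n` the active state, so `k_mn` is the
#' inactive-to-active rate.
#'
#' @param k_mn Rate inactive -> active (s^-1, > 0).
#' @param k_nm Rate active -> inactive (s^-1, > 0).
#' @param temperature Absolute temperature in K (default 298.15).
#' @param gas_constant Gas constant in kcal mol^-1 K^-1.
#' @return An object of class `slow_exchange_params` with elements `k_mn`,
#'   `k_nm`, `k_s`, `p_active`, `p_inactive`, `temperature` and `delta_g`, a
#'   list of both directed differences (kcal mol^-1):
#'   `active_minus_inactive` (= G_active - G_inactive) and
#'   `inactive_minus_active` (its negation). Detailed balance
#'   `p_active * k_nm = p_inactive * k_mn` holds by construction.
#' @examples
#' derive_slow_exchange_thermo(1.08, 1.23)  # k_s = 2.31, p_active ~ 0.47
#' @export
derive_slow_exchange_thermo <- function(k_mn, k_nm, temperature = 298.15,
                                        gas_constant = gas_constant_kcal) {
  if (!is.numeric(k_mn) || k_mn <= 0 || !is.numeric(k_nm) || k_nm <= 0)
    stop("both rates must be positive", call. = FALSE)
  if (temperature <= 0) stop("`temperature` must be positive", call. = FALSE)
  k_s <- k_mn + k_nm
  p_active <- k_mn / k_s
  p_inactive <- k_nm / k_s
  rt <- gas_constant * temperature
  dg_active <- -rt * log(p_active / p_inactive)  # G_active - G_inactive
  structure(list(
    k_mn = k_mn, k_nm = k_nm, k_s = k_s,
    p_active = p_active, p_inactive = p_inactive,
    temperature = temperature,
    delta_g = list(active_minus_inactive = dg_active,
                   inactive_minus_active = -dg_active)),
    class = "slow_exchange_params")
}

#' @export
print.slow_exchange_params <- function(x, ...) {
  cat("Slow two-state exchange (inactive <-> active)\n")
  cat(sprintf("  k_mn (inactive->active): %.4g s^-1\n", x$k_mn))
  cat(sprintf("  k_nm (active->inactive): %.4g s^-1\n", x$k_nm))
  cat(sprintf("  k_s = %.4g s^-1, p_active = %.3f, p_inactive = %.3f\n",
              x$k_s, x$p_active, x$p_inactive))
  cat(sprintf("  dG (active - inactive) = %+.3f kcal/mol at %.2f K\n",
              x$delta_g$active_minus_inactive, x$temperature))
  invisible(x)
}

#' Convert a chemical-shift difference from ppm to angular frequency
#'
#' \eqn{\Delta\omega = 2\pi f \Delta\delta} with `f` the spectrometer
#' frequency in MHz, so a ppm difference maps to Hz before the `2*pi`.
#'
#' @param delta_delta Shift difference in ppm.
#' @param spectrometer_freq Larmor frequency of the observed nucleus in MHz
#'   (> 0).
#' @return Angular frequency difference in rad s^-1.
#' @export
delta_omega_from_ppm <- function(delta_delta, spectrometer_freq) {
  stopifnot(spectrometer_freq > 0)
  2 * pi * delta_delta * spectrometer_freq
}

#' Inverse of [delta_omega_from_ppm()]
#'
#' @param delta_omega Angular frequency difference in rad s^-1.
#' @param spectrometer_freq Larmor frequency in MHz (> 0).
#' @return Shift difference in ppm.
#' @export
ppm_from_delta_omega <- function(delta_omega, spectrometer_freq) {
  stopifnot(spectrometer_freq > 0)
  delta_omega / (2 * pi * spectrometer_freq)
}
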