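#' Ground truth describing a complete synthetic study
#'
#' Bundles every parameter the generators need: slow (fold-switch) rates per
#' ligand condition, fast (domain-motion) exchange parameters per resonance
#' and condition, longitudinal rates, resonance positions, spectrometer
#' fields and the noise scale. Defaults reproduce the study conditions of
#' the 19F-labelled fold-switching mannosyltransferase system this package
#' was built around: two fields (564 and 659 MHz), constant-time delay 3.84 ms,
#' 25 degrees C, slow rates of order 1-10 s^-1, fast rates of order
#' 4000-8000 s^-1 and shift differences of 1.2-2.9 ppm.
#'
#' Intrinsic transverse rates per resonance and field are free inputs (they
#' are not derivable from the exchange parameters); the defaults emulate the
#' observed field-dependent line broadening of the active-state resonance.
#'
#' @param fields Spectrometer 19F frequencies in MHz.
#' @param constant_time Constant-time CPMG delay in seconds.
#' @param temperature Kelvin.
#' @param noise_sigma Additive Gaussian noise scale relative to `I_0`.
#' @param slow Per-condition list with `k_mn` (inactive -> active) and
#'   `k_nm` (active -> inactive), s^-1.
#' @param fast Per-resonance, per-condition list with `k_i`, `p_extended`,
#'   `p_compact`, `delta_delta` (ppm) and `minor` (which conformer is the
#'   sparse one).
#' @param shifts Per-condition named vector of resonance centers (ppm).
#' @param r1 Per-condition named vector of longitudinal rates (s^-1).
#' @param r2_0 Per-resonance list of named-per-field intrinsic transverse
#'   rates (s^-1).
#' @param linewidth_r2 Per-condition named vector of effective transverse
#'   rates used when drawing slow-exchange 1D spectra (s^-1).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(
    fields = c(564, 659),
    constant_time = 0.00384,
    temperature = 298.15,
    noise_sigma = 0.01,
    slow = list(
      apo    = list(k_mn = 1.08, k_nm = 1.23),
      ligand = list(k_mn = 4.2,  k_nm = 8.3)),
    fast = list(
      active = list(
        apo    = list(k_i = 4300, p_extended = 0.81, p_compact = 0.19,
                      delta_delta = 1.2, minor = "compact"),
        ligand = list(k_i = 7300, p_extended = 0.70, p_compact = 0.30,
                      delta_delta = 1.2, minor = "compact")),
      inactive = list(
        apo    = list(k_i = 8000, p_extended = 0.009, p_compact = 0.991,
                      delta_delta = 2.9, minor = "extended"),
        ligand = list(k_i = 5100, p_extended = 0.026, p_compact = 0.974,
                      delta_delta = 2.9, minor = "extended"))),
    shifts = list(apo    = c(active = -82.7, inactive = -84.1),
                  ligand = c(active = -82.6, inactive = -84.3)),
    r1 = list(apo    = c(active = 1.5, inactive = 1.5),
              ligand = c(active = 1.5, inactive = 1.5)),
    r2_0 = list(active   = c("564" = 30, "659" = 45),
                inactive = c("564" = 25, "659" = 35)),
    linewidth_r2 = list(apo    = c(active = 120, inactive = 80),
                        ligand = c(active = 140, inactive = 100))) {
  for (cond in names(fast[[1]])) {
    for (res in names(fast)) {
      fc <- fast[[res]][[cond]]
      if (abs(fc$p_extended + fc$p_compact - 1) > 1e-8)
        stop("fast populations must sum to 1 for ", res, "/", cond, call. = FALSE)
    }
  }
  stopifnot(all(fields > 0), constant_time > 0, temperature > 0,
            noise_sigma >= 0)
  structure(list(fields = fields, constant_time = constant_time,
                 temperature = temperature, noise_sigma = noise_sigma,
                 slow = slow, fast = fast, shifts = shifts, r1 = r1,
                 r2_0 = r2_0, linewidth_r2 = linewidth_r2),
            class = "ground_truth")
}

#' CPMG dispersion dataset
#'
#' @param nu_cpmg Refocusing frequencies (s^-1, > 0).
#' @param intensity Peak intensities (a.u.).
#' @param spectrometer_freq Field in MHz.
#' @param constant_time `T_CPMG` in seconds.
#' @param reference_intensity `I_0` (> 0).
#' @param condition,resonance Labels.
#' @param grid_tol Relative tolerance for checking that each `nu_cpmg` sits
#'   on the realizable grid `n / (2 * constant_time)`; off-grid values
#'   within 1 percent are accepted with a warning.
#' @return An object of class `cpmg_dataset`.
#' @export
cpmg_dataset <- function(nu_cpmg, intensity, spectrometer_freq,
                         constant_time, reference_intensity = 1,
                         condition = "apo", resonance = "active",
                         grid_tol = 0.01) {
  stopifnot(length(nu_cpmg) == length(intensity), length(nu_cpmg) >= 2,
            all(nu_cpmg > 0), all(is.finite(intensity)),
            constant_time > 0, reference_intensity > 0,
            spectrometer_freq > 0)
  if (anyDuplicated(nu_cpmg))
    stop("duplicate nu_cpmg values", call. = FALSE)
  n <- nu_cpmg * 2 * constant_time
  off <- abs(n - round(n)) / n
  if (any(off > grid_tol))
    stop("nu_cpmg values not on the realizable grid n/(2*T_CPMG): ",
         paste(signif(nu_cpmg[off > grid_tol], 6), collapse = ", "),
         call. = FALSE)
  if (any(off > 1e-6 & off <= grid_tol))
    warning("nu_cpmg values slightly off the realizable grid accepted within tolerance")
  o <- order(nu_cpmg)
  structure(list(nu_cpmg = nu_cpmg[o], intensity = intensity[o],
                 spectrometer_freq = spectrometer_freq,
                 constant_time = constant_time,
                 reference_intensity = reference_intensity,
                 condition = condition, resonance = resonance),
            class = "cpmg_dataset")
}

#' @export
print.cpmg_dataset <- function(x, ...) {
  cat(sprintf("CPMG dataset: %s/%s at %g MHz, T_CPMG = %g ms, %d points (nu %.4g-%.4g s^-1)\n",
              x$resonance, x$condition, x$spectrometer_freq,
              1000 * x$constant_time, length(x$nu_cpmg),
              min(x$nu_cpmg), max(x$nu_cpmg)))
  invisible(x)
}

# Deterministic log-uniform subsample of the realizable echo counts
# n in 1..n_max, endpoints forced, greedy dedup upwards.
.cpmg_echo_grid <- function(n_points, n_max) {
  if (n_points > n_max)
    stop("requested more points than realizable echo counts", call. = FALSE)
  targets <- exp(seq(log(1), log(n_max), length.out = n_points))
  picked <- integer(0)
  for (t in targets) {
    n <- max(1L, round(t))
    while (n %in% picked && n < n_max) n <- n + 1L
    if (!(n %in% picked)) picked <- c(picked, n)
  }
  while (length(picked) < n_points) {
    free <- setdiff(seq_len(n_max), picked)
    picked <- c(picked, free[1])
  }
  sort(picked)
}

.fast_system <- function(truth, resonance, condition, field) {
  fc <- truth$fast[[resonance]][[condition]]
  if (is.null(fc)) stop("unknown resonance/condition", call. = FALSE)
  p_minor <- min(fc$p_extended, fc$p_compact)
  dw <- delta_omega_from_ppm(fc$delta_delta, field)
  r20 <- truth$r2_0[[resonance]][[as.character(field)]]
  if (is.null(r20)) stop("no intrinsic R2 for field ", field, call. = FALSE)
  # site a = major conformer (the observed line position), site b = minor
  two_site_system(omega_a = 0, omega_b = dw, p_a = 1 - p_minor,
                  k_ex = fc$k_i, r2_a = r20, r2_b = r20)
}

#' Generate a synthetic CPMG dispersion series
#'
#' The refocusing frequencies are realizable multiples `n / (2 * T_CPMG)`;
#' the default grid takes `n_points` log-uniform echo counts between 1 and
#' the largest count keeping `nu_cpmg` near 6000 s^-1 (46 for the default
#' `T_CPMG`, giving 130.2 to 5989.6 s^-1). Intensities are
#' `I_0 exp(-T_CPMG * R_2,eff(nu))` with `R_2,eff` from the
#' Bloch-McConnell propagator (or the Carver-Richards closed form when
#' `r2_method = "closed_form"`), plus seeded Gaussian noise of scale
#' `noise_sigma * I_0`.
#'
#' @param truth A [ground_truth()].
#' @param resonance `"active"` or `"inactive"`.
#' @param condition `"apo"` or `"ligand"`.
#' @param field Spectrometer frequency in MHz (one of `truth$fields`).
#' @param n_points Number of dispersion points (>= 4; default 14).
#' @param seed Integer seed (mandatory; generators have no implicit
#'   randomness).
#' @param noise_sigma Overrides `truth$noise_sigma` if given.
#' @param r2_method `"bloch_mcconnell"` (default) or `"closed_form"`.
#' @return A [cpmg_dataset()].
#' @export
generate_cpmg_series <- function(truth, resonance, condition, field,
                                 n_points = 14, seed,
                                 noise_sigma = NULL,
                                 r2_method = c("bloch_mcconnell", "closed_form")) {
  stopifnot(inherits(truth, "ground_truth"), n_points >= 4)
  r2_method <- match.arg(r2_method)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (is.null(noise_sigma)) noise_sigma <- truth$noise_sigma
  tt <- truth$constant_time
  n_max <- floor(6000 * 2 * tt)
  echoes <- .cpmg_echo_grid(n_points, n_max)
  nu <- echoes / (2 * tt)
  sys <- .fast_system(truth, resonance, condition, field)
  r2eff <- if (r2_method == "bloch_mcconnell") {
    simulate_cpmg(sys, echoes, tt, observed_site = "a")
  } else {
    fc <- truth$fast[[resonance]][[condition]]
    p_minor <- min(fc$p_extended, fc$p_compact)
    .cr_r2(nu, fc$k_i, p_minor, delta_omega_from_ppm(fc$delta_delta, field),
           truth$r2_0[[resonance]][[as.character(field)]])
  }
  i0 <- 1
  intensity <- i0 * exp(-tt * r2eff)
  if (noise_sigma > 0)
    intensity <- intensity +
      withr::with_seed(seed, stats::rnorm(length(nu), 0, noise_sigma * i0))
  cpmg_dataset(nu, intensity, spectrometer_freq = field,
               constant_time = tt, reference_intensity = i0,
               condition = condition, resonance = resonance)
}

#' Saturation-transfer series container
#'
#' @param taus Saturation times (s), strictly increasing, >= 4 points.
#' @param intensities Observed intensities (a.u.).
#' @param observed,saturated Resonance labels.
#' @param condition Condition label.
#' @param r1 Longitudinal rate of the observed resonance (s^-1), required
#'   for fitting.
#' @param r1_provenance How `r1` was obtained (`"fit"`, `"user"`,
#'   `"truth"`).
#' @param i0 Optional true reference intensity.
#' @return An object of class `saturation_series`.
#' @export
saturation_series <- function(taus, intensities, observed, saturated,
                              condition = "apo", r1 = NULL,
                              r1_provenance = "user", i0 = NULL) {
  stopifnot(length(taus) == length(intensities), length(taus) >= 4,
            all(taus >= 0), all(diff(taus) > 0))
  structure(list(taus = taus, intensities = intensities,
                 observed = observed, saturated = saturated,
                 condition = condition, r1 = r1,
                 r1_provenance = r1_provenance, i0 = i0),
            class = "saturation_series")
}

#' Generate a synthetic saturation-transfer decay
#'
#' Default 8 saturation times log-spaced between 25 ms and 1 s; intensities
#' follow the slow-exchange closed form with the truth's directed rate out
#' of the observed state, plus seeded Gaussian noise.
#'
#' @param truth A [ground_truth()].
#' @param observed Observed resonance (`"active"` or `"inactive"`); the
#'   partner resonance is the saturated one.
#' @param condition Condition label.
#' @param seed Integer seed.
#' @param n_taus Number of saturation times (default 8).
#' @param tau_range Range in seconds (default `c(0.025, 1)`).
#' @param noise_sigma Overrides `truth$noise_sigma` if given.
#' @return A [saturation_series()] carrying the truth `r1` and `i0 = 1`.
#' @export
generate_saturation_series <- function(truth, observed, condition, seed,
                                       n_taus = 8, tau_range = c(0.025, 1),
                                       noise_sigma = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (is.null(noise_sigma)) noise_sigma <- truth$noise_sigma
  saturated <- setdiff(c("active", "inactive"), observed)
  if (length(saturated) != 1L) stop("unknown `observed` label", call. = FALSE)
  sl <- truth$slow[[condition]]
  # rate out of the observed state
  k_out <- if (observed == "active") sl$k_nm else sl$k_mn
  r1 <- truth$r1[[condition]][[observed]]
  taus <- exp(seq(log(tau_range[1]), log(tau_range[2]), length.out = n_taus))
  i0 <- 1
  y <- slow_exchange_intensity(taus, i0, k_out, r1)
  if (noise_sigma > 0)
    y <- y + withr::with_seed(seed, stats::rnorm(length(taus), 0, noise_sigma * i0))
  saturation_series(taus, y, observed = observed, saturated = saturated,
                    condition = condition, r1 = r1,
                    r1_provenance = "truth", i0 = i0)
}

#' Inversion-recovery series container
#'
#' @param taus Recovery delays (s), strictly increasing, >= 5 points.
#' @param intensities Intensities (a.u.).
#' @param resonance,condition Labels.
#' @return An object of class `relaxation_series`.
#' @export
relaxation_series <- function(taus, intensities, resonance = "active",
                              condition = "apo") {
  stopifnot(length(taus) == length(intensities), length(taus) >= 5,
            all(taus >= 0), all(diff(taus) > 0))
  structure(list(taus = taus, intensities = intensities,
                 resonance = resonance, condition = condition),
            class = "relaxation_series")
}

#' Generate a synthetic inversion-recovery series
#'
#' `I(tau) = A - B exp(-R1 tau)` with `A = 1` and `B = 2` (perfect
#' inversion) plus seeded Gaussian noise; at least 10 delays between 25 and
#' 800 ms.
#'
#' @param truth A [ground_truth()].
#' @param resonance,condition Labels.
#' @param seed Integer seed.
#' @param n_taus Number of delays (default 10).
#' @param tau_range Delay range in seconds (default `c(0.025, 0.8)`).
#' @param noise_sigma Overrides `truth$noise_sigma` if given.
#' @return A [relaxation_series()].
#' @export
generate_inversion_recovery <- function(truth, resonance, condition, seed,
                                        n_taus = 10,
                                        tau_range = c(0.025, 0.8),
                                        noise_sigma = NULL) {
  stopifnot(inherits(truth, "ground_truth"), n_taus >= 10)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (is.null(noise_sigma)) noise_sigma <- truth$noise_sigma
  r1 <- truth$r1[[condition]][[resonance]]
  taus <- seq(tau_range[1], tau_range[2], length.out = n_taus)
  y <- 1 - 2 * exp(-r1 * taus)
  if (noise_sigma > 0)
    y <- y + withr::with_seed(seed, stats::rnorm(length(taus), 0, noise_sigma))
  relaxation_series(taus, y, resonance = resonance, condition = condition)
}

#' Bound fraction from the exact two-component binding quadratic
#'
#' @param protein,ligand Total concentrations (same units as `kd`, >= 0).
#' @param kd Dissociation constant.
#' @return Fraction of protein bound, in `[0, 1]`.
#' @export
bound_fraction <- function(protein, ligand, kd) {
  stopifnot(protein > 0, all(ligand >= 0), kd >= 0)
  s <- protein + ligand + kd
  pmin(1, pmax(0, (s - sqrt(s^2 - 4 * protein * ligand)) / (2 * protein)))
}

#' Generate a titration series of 1D spectra
#'
#' Emulates a ligand titration: the bound fraction at each ligand
#' concentration follows the exact binding quadratic; resonance centers,
#' slow rates and linewidths interpolate linearly between the apo and
#' ligand-saturated truth with the bound fraction; each spectrum is the
#' steady-state two-site (active/inactive) lineshape plus seeded noise.
#' With a sub-micromolar `kd` the spectra stop changing once the ligand
#' exceeds the protein stoichiometry.
#'
#' @param truth A [ground_truth()].
#' @param ligand_concentrations Ligand concentrations in uM (>= 0).
#' @param protein_concentration Protein concentration in uM (default 100).
#' @param kd Dissociation constant in uM (default 0.23).
#' @param seed Integer seed.
#' @param field Spectrometer frequency in MHz.
#' @param ppm_axis Axis for the synthesized spectra.
#' @param noise_sigma Overrides `truth$noise_sigma` if given (relative to
#'   the maximum apo intensity).
#' @return A list of [spectrum1d()], one per concentration, with the bound
#'   fractions attached as attribute `bound_fraction`.
#' @export
generate_titration_spectra <- function(truth, ligand_concentrations,
                                       protein_concentration = 100,
                                       kd = 0.23, seed, field = 659,
                                       ppm_axis = seq(-86, -80.5, by = 0.004),
                                       noise_sigma = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (any(ligand_concentrations < 0))
    stop("negative ligand concentration", call. = FALSE)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (is.null(noise_sigma)) noise_sigma <- truth$noise_sigma
  fb <- bound_fraction(protein_concentration, ligand_concentrations, kd)
  lerp <- function(a, b, f) a + f * (b - a)
  specs <- vector("list", length(fb))
  scale_ref <- NULL
  for (i in seq_along(fb)) {
    f <- fb[i]
    sh <- lerp(truth$shifts$apo, truth$shifts$ligand, f)
    kmn <- lerp(truth$slow$apo$k_mn, truth$slow$ligand$k_mn, f)
    knm <- lerp(truth$slow$apo$k_nm, truth$slow$ligand$k_nm, f)
    lw <- lerp(truth$linewidth_r2$apo, truth$linewidth_r2$ligand, f)
    p_active <- kmn / (kmn + knm)
    sys <- two_site_system(
      omega_a = delta_omega_from_ppm(sh[["active"]], field),
      omega_b = delta_omega_from_ppm(sh[["inactive"]], field),
      p_a = p_active, k_ex = kmn + knm,
      r2_a = lw[["active"]], r2_b = lw[["inactive"]],
      r1_a = truth$r1$apo[["active"]], r1_b = truth$r1$apo[["inactive"]])
    sp <- simulate_spectrum(sys, ppm_axis, field)
    if (is.null(scale_ref)) scale_ref <- max(sp$intensity)
    if (noise_sigma > 0)
      sp$intensity <- sp$intensity +
        withr::with_seed(seed + i, stats::rnorm(length(ppm_axis), 0,
                                                noise_sigma * scale_ref))
    specs[[i]] <- sp
  }
  attr(specs, "bound_fraction") <- fb
  specs
}
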