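# Shared helpers: study-condition truth and small constructors used across
# the test files. All randomness in tests flows through explicit seeds.

study_truth <- function(...) ground_truth(...)

# two-site fast-exchange system matching one resonance/condition of a truth
fast_sys <- function(truth, resonance, condition, field) {
  fc <- truth$fast[[resonance]][[condition]]
  p_minor <- min(fc$p_extended, fc$p_compact)
  two_site_system(
    omega_a = 0,
    omega_b = delta_omega_from_ppm(fc$delta_delta, field),
    p_a = 1 - p_minor, k_ex = fc$k_i,
    r2_a = truth$r2_0[[resonance]][[as.character(field)]],
    r2_b = truth$r2_0[[resonance]][[as.character(field)]])
}

# synthetic two-Lorentzian spectrum (plus optional seeded noise) with known
# peak truth; widths in Hz, areas proportional to `pops`
two_peak_spectrum <- function(centers = c(-82.7, -84.1), fwhm_hz = c(40, 25),
                              pops = c(0.47, 0.53), field = 564,
                              noise = 0, seed = 1,
                              ppm = seq(-86, -80.5, by = 0.002)) {
  fwhm_ppm <- fwhm_hz / field
  # area_i proportional to pops => amplitude = 2*area/(pi*fwhm)
  areas_hz <- pops / sum(pops)
  amps <- 2 * areas_hz / (pi * fwhm_hz)
  y <- .lz(ppm, centers[1], fwhm_ppm[1], amps[1]) +
    .lz(ppm, centers[2], fwhm_ppm[2], amps[2])
  if (noise > 0)
    y <- y + withr::with_seed(seed, rnorm(length(ppm), 0, noise * max(y)))
  list(spectrum = spectrum1d(ppm, y, field),
       truth = list(centers = centers, fwhm_hz = fwhm_hz,
                    areas_hz = areas_hz, amplitudes = amps))
}

.lz <- function(ppm, center, fwhm_ppm, amp) {
  amp / (1 + (2 * (ppm - center) / fwhm_ppm)^2)
}
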