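---
title: "Quantifying two-timescale conformational exchange from 19F NMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying two-timescale conformational exchange from 19F NMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorex)
```

## The problem

A single ^19^F reporter attached to a protein that interconverts between
conformations produces a remarkably information-rich 1D spectrum. When the
exchange between two states is *slow* on the chemical-shift timescale
(seconds), each state shows its own resonance and the populations can be
read off peak integrals; the rates are accessible by saturation transfer.
When exchange is *fast-to-intermediate* (milliseconds), a single resonance
remains, but its effective transverse relaxation rate depends on how fast a
CPMG pulse train refocuses the dephasing — the relaxation-dispersion
experiment.

`fluorex` implements the complete quantitative chain for such a system:
converting constant-time CPMG intensities to effective rates, the
Luz-Meiboom and Carver-Richards dispersion models with a global fit across
magnetic fields and ligand conditions, Forsen-Hoffman saturation-transfer
fitting, monoexponential inversion-recovery fitting, double-Lorentzian
deconvolution, and the assembly of the resulting rates and populations into
a four-state thermodynamic model (inactive/active manifolds, each in fast
compact/extended exchange). A numerical Bloch-McConnell simulator and a
fully seeded synthetic-data generator make every stage testable without any
experimental data.

The motivating system is a ^19^F-labelled bacterial mannosyltransferase
whose activation proceeds through a secondary-structure fold-switch: two
resonances near −82.7 ppm (active) and −84.1 ppm (inactive) in slow
(~1–13 s^−1^) exchange, each additionally broadened by millisecond
(~4000–8000 s^−1^) domain motions. The generator defaults encode those
study conditions.

## Models

**Effective rate (constant-time CPMG).** With a constant relaxation delay
$T_\mathrm{CPMG}$ and reference intensity $I_0$ acquired without the delay,

$$R_{2,\mathrm{eff}}(\nu_\mathrm{CPMG}) = -\frac{1}{T_\mathrm{CPMG}}
\ln\frac{I(\nu_\mathrm{CPMG})}{I_0},\qquad
\nu_\mathrm{CPMG} = \frac{1}{2\tau_\mathrm{CPMG}} = \frac{n}{2\,T_\mathrm{CPMG}},$$

so only frequencies on the grid $n/(2T_\mathrm{CPMG})$ are realizable
($n$ = number of 180° pulses). Defaults: $T_\mathrm{CPMG}$ = 3.84 ms, 14
points between 130.2 and 5989.6 s^−1^ (`n` = 1…46, log-uniform with forced
endpoints), two fields (564 and 659 MHz ^19^F).

**Luz-Meiboom (fast limit, single field).**
$R_{2,\mathrm{eff}} = \frac{c}{k_\mathrm{app}}\big[1 -
\frac{4\nu}{k_\mathrm{app}}\tanh\frac{k_\mathrm{app}}{4\nu}\big] + R_{2,0}$
with $c = p_A p_B \Delta\omega^2$. Populations and shift difference cannot
be separated; `fit_luz_meiboom()` reports only the composite and flags flat
dispersions as unidentifiable.

**Carver-Richards (all regimes, global).** The closed form used by
`carver_richards_r2()` is

$$R_{2,\mathrm{eff}} = R_{2,0} + \tfrac12\Big(k_i - 2\nu\,
\mathrm{arcosh}\big(D_+\cosh\eta_+ - D_-\cos\eta_-\big)\Big),$$

with $\psi = (p_B-p_A)^2k_i^2 - \Delta\omega^2 + 4p_Ap_Bk_i^2$,
$\xi = 2\Delta\omega(p_B-p_A)k_i$,
$\eta_\pm = (\sqrt8\,\nu)^{-1}\sqrt{\pm\psi+\sqrt{\psi^2+\xi^2}}$ and
$D_\pm = \tfrac12[\pm1 + (\psi+2\Delta\omega^2)/\sqrt{\psi^2+\xi^2}]$.
The $\eta_\pm$ prefactor $1/(\sqrt8\,\nu)$ equals $\tau_\mathrm{CPMG}/\sqrt2$,
the standard form; correctness is certified against the Bloch-McConnell
propagator rather than against any printed rendering of the algebra.

`fit_carver_richards_global()` solves one weighted least-squares problem
over up to four datasets per resonance with the sharing scheme used in
two-field studies: $|\Delta\delta|$ shared across everything (ligand
binding is assumed not to change the exchanging conformations themselves),
$(k_i, p)$ shared across fields within a condition (kinetics are field
independent), $R_{2,0}$ free per dataset (linewidths are field dependent
through chemical-shift anisotropy). $\Delta\omega$ is recomputed per
dataset as $2\pi f |\Delta\delta|$.

**Saturation transfer (slow exchange).** With the partner resonance held
saturated, the observed intensity decays as

$$I_m(\tau) = \frac{I_m(0)}{k_{mn}+R_{1,m}}\Big[k_{mn}
e^{-\tau(k_{mn}+R_{1,m})} + R_{1,m}\Big],$$

towards the plateau $I_0 R_1/(k+R_1)$. `fit_saturation_transfer()` frees
$I_0$ and $k_{mn}$ and fixes $R_{1,m}$ from the inversion-recovery fit of
the same resonance and condition (the provenance is recorded). The two
reciprocal experiments give both directed rates, from which
$k_s = k_{mn}+k_{nm}$, $p_n = k_{mn}/k_s$ and
$\Delta G = -RT\ln(p_n/p_m)$ follow (`derive_slow_exchange_thermo()`).

**Four-state assembly.** Because the within-manifold motions (ms) are three
orders of magnitude faster than the fold-switch (s), the fast equilibria
are treated as conditionally independent within each slow manifold: joint
populations are products of the manifold population and the conditional
population, and free-energy levels are $-RT\ln(p/p_\mathrm{ref})$ relative
to the most populated state.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `constant_time` | 0.00384 | s | constant-time CPMG delay; fixes the realizable frequency grid |
| fields | 564, 659 | MHz | ^19^F Larmor frequencies of the two spectrometers |
| `temperature` | 298.15 | K | experiments at 25 °C; enters only the free energies |
| gas constant | 1.9872e-3 | kcal mol^−1^ K^−1^ | free energies reported in kcal/mol |
| `noise_sigma` | 0.01 | fraction of `I_0` | generator noise scale; makes all fits comfortably identifiable |
| R1 | 1.5 | s^−1^ | longitudinal rate assumed for synthetic decays |
| intrinsic R2 | 25–45 | s^−1^ | free per resonance and field; emulates CSA line broadening at higher field |

The bounds used by all fitters are $p\in[0,1]$ (minor population restricted
to $[0,0.5]$ in the dispersion fit, which the population-swap symmetry of
the model permits without loss), rates in $[0, 10^7]$ s^−1^ and
$|\Delta\delta|\in[0,20]$ ppm.

## The synthetic-data generator

`ground_truth()` bundles the study conditions: slow rates 1.08/1.23 s^−1^
(ligand-free) and 4.2/8.3 s^−1^ (ligand-saturated); fast exchange at
4300–8000 s^−1^ with minor populations 0.009–0.30 and shift differences
1.2/2.9 ppm; resonances at −82.7/−84.1 ppm (shifting to −82.6/−84.3 with
ligand). Every generator takes an explicit integer seed — there is no
implicit randomness — and noiseless output inverts exactly through the
corresponding model evaluator.

What the generator emulates: the acquisition geometry (14 realizable CPMG
frequencies at two fields, 8 log-spaced saturation times in 25–1000 ms,
10 inversion-recovery delays in 25–800 ms), additive thermal noise
(i.i.d. Gaussian on intensities, one variance for all points), ligand
titration through the exact two-component binding quadratic
(K~D~ = 0.23 µM against 100 µM protein saturates just above
stoichiometry), and field-dependent line broadening via per-field intrinsic
rates. What it does **not** emulate: pulse imperfections, finite-strength
saturation, scalar couplings, baseline distortions, temperature drift, or
correlated noise. Passing recovery tests therefore demonstrate the
estimators are consistent and identifiable under the stated noise model —
not that real spectra are free of the systematic effects above.

## Numerical choices

- **Bloch-McConnell propagation.** The 2×2 complex evolution operator is
  exponentiated by eigendecomposition, so the CPMG train
  $[\tau/2-180°-\tau/2]^n$ is evolved piecewise exactly (no time-stepping
  error); 180° pulses are ideal (complex conjugation). Saturation transfer
  integrates the longitudinal equations with the saturated site pinned at
  zero, relative tolerance $10^{-9}$.
- **Detection conventions.** `simulate_cpmg()` offers two observables.
  `"signal"` is the experimental one: the observed-site magnitude after the
  train referenced to its equilibrium value, which carries the
  initial-condition projection onto the decaying eigenmodes — exactly as a
  measured peak does. `"eigenvalue"` is the asymptotic decay rate of the
  echo-cycle propagator, the projection-free quantity that the
  Carver-Richards expression describes; it is the like-for-like comparison
  when certifying the closed form (agreement to machine precision), while
  the signal observable can differ from the closed form by several percent
  in strongly intermediate exchange. The generator uses `"signal"`, so
  synthetic data carry the same small systematic a real constant-time
  measurement does; the dispersion-fit recovery tolerances absorb it.
- **arcosh guard.** Floating-point cancellation can push the arcosh
  argument marginally below 1; violations within $10^{-9}$ are clamped to
  1, larger ones raise an error rather than silently continuing.
- **Multi-start.** The Carver-Richards objective has well-known degeneracy
  valleys (rate against population against shift). Fits start from the grid
  $k_i\in\{10^2,10^3,10^4\}\times p_\mathrm{minor}\in\{0.01,0.1,0.3\}
  \times|\Delta\delta|\in\{1,3\}$ (18 starts, short iteration budget), the
  best objective is polished with a long budget, and exact ties resolve to
  the smaller $k_i$.
- **Weights and uncertainties.** Uniform weights by default (per-point
  uncertainties are rarely available for 1D ^19^F data; they are accepted
  when supplied). Parameter uncertainties come from the Jacobian covariance
  at the optimum and, side by side, from a seeded residual bootstrap —
  neither is claimed to replicate any particular published error
  convention.
- **Degenerate inputs.** Flat dispersions pin $c=0$ and flag the exchange
  parameters unidentifiable; constant inversion-recovery traces and flat
  saturation decays are flagged, never silently fitted; a merged two-peak
  deconvolution re-initializes from the two highest separated local maxima;
  ties between identical overlapping peaks break by descending ppm.
- **Display rounding** is round-half-to-even at the printed precision;
  machine outputs keep full precision.

## Design decisions taken where the design was open

- $R_{2,0}$ is free per dataset rather than shared across conditions — the
  most conservative reading of the sharing scheme; sharing it would couple
  ligand-induced broadening into the exchange parameters.
- The inversion-recovery amplitude is fitted (imperfect inversion) rather
  than fixed at twice the equilibrium intensity.
- The deconvolution model adds a constant baseline term to the
  double-Lorentzian: real 1D spectra have offsets, and the term costs one
  parameter.
- Free energies are reported with explicit direction tags; the per-state
  report rows carry the rate *into* the row state, the population *of* the
  row state, and $RT\ln(p_\mathrm{row}/p_\mathrm{other})$, which reproduces
  the sign convention of the reference tables (−0.070/+0.070 kcal/mol from
  p = 0.47/0.53).
- Titration intensities can be corrected for stock-addition dilution by the
  volume ratio (`dilution_correct()`), the simplest defensible model.
- The temperature (298.15 K) and gas constant (1.9872×10^−3^
  kcal mol^−1^ K^−1^) are configuration defaults, overridable.

## Problem sizes

The test-suite recovery studies use the acquisition geometry above with 20
noise seeds for the dispersion and saturation studies, a 100-point random
parameter grid (rates $10^2$–$10^4$ s^−1^, minor populations 0.005–0.5,
shift differences 0.5–3 ppm, both fields) for the oracle-equivalence check,
and a full two-condition, two-field fixture for the end-to-end pipeline
run. These sizes were chosen to make medians stable while keeping any
single study in the tens of seconds.

## Known limitations

- Two sites only; no three-state closed forms, no off-resonance R1rho.
- Ideal pulses and ideal (instantaneous, complete) saturation; the
  finite-B1 case is an extension point, not implemented.
- No model selection between exchange topologies — the four-state network
  is assembled from the two-state fits under the timescale-separation
  assumption, not inferred.
- Field-dependent broadening is an input, not derived from
  chemical-shift-anisotropy theory.
- Barrier heights are not estimated: rates alone do not fix them without a
  prefactor assumption.
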