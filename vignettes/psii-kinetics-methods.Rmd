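---
title: "Models and methods: PSII photoinactivation, repair and NPQ kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: PSII photoinactivation, repair and NPQ kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psiikinetics)
```

## Scope and assumptions

This package analyses FRR-fluorometry treatment experiments on
phytoplankton: a dark-acclimated culture is held through 300-s measurement
intervals under a programmed light sequence (dark, growth light, several
treatment periods, low-light recovery), with an FRR induction at the end of
each interval. Three kinetic layers are modelled and fitted:

1. **Pool dynamics.** Active PSII is lost first-order in photon dose
   (`k_pi = sigma_i * E(I)`, with `sigma_i` the target size in
   m^2 photon^-1) and regained by repair. The package carries both the
   classical two-state model (all PSII active at t0) and the inactive-pool
   variant, `dA/dt = -k_pi A + k_recinact (A0 + i0 - A)`, in which a
   standing pool `i0` of photoinactivated-but-intact PSII is already repair
   substrate. `i0` is estimated independently as the clamped excess of
   PsbA protein over flash-yield active centres. The two models are nested
   (`i0 = 0`), and both closed forms are validated in the test suite
   against numerical integration (deSolve) to 1e-8 relative error.
   Assumptions: total pool `A0 + i0` is conserved within a treatment (no
   net synthesis or degradation of PSII units on the 45-min scale), rate
   constants are constant within a light phase, and repair is fully
   blocked by lincomycin.
2. **Quenching dynamics.** qP responds instantaneously to irradiance
   through a saturation law with half-saturation `ke_qp`. Y(NPQ) rises
   first-order (rate `k_npq`) towards a light-saturating amplitude
   `I/(ke_npq + I)`, plus a slow zero-order phase `k_npqslow * t_cum` in
   cumulative illuminated time; it relaxes first-order (`kr_npq`) after a
   drop in light. The zero-order phase is additive to Y(NPQ): it
   represents the accumulating, xanthophyll-linked component, and the
   whole yield is clipped to [0, 1) since Y(NPQ) is a quantum yield. The
   slow phase is switched off under dithiothreitol.
3. **Single-trace optics.** FRR flashlet inductions follow the
   cumulative-closure model with connectivity `rho`: per flashlet of dose
   `E` (quanta A^-2), the closed fraction updates as
   `C <- C + E sigma (1-C)(1-rho)/(1-rho C)`, and fluorescence is
   `F0 + (FM-F0) C (1-rho)/(1-rho C)`. Reopening during the 128-us train
   is neglected. The post-train reopening tail is a two-phase exponential
   with lifetimes `tau1 >= tau2`. The per-flashlet dose must be carried
   with the trace: the cross section is identifiable only jointly with it.

## Time conventions

Model time restarts at each phase onset: induction time `t` runs from
treatment onset, relaxation time from recovery onset, and `t_cum` counts
cumulative treatment (illuminated) time. The pre-treatment dark and growth
intervals represent the growth-acclimated steady state: pools and Y(NPQ)
are held at their t0 values until the treatment starts. This makes the
simulator's t0 state exactly the ground truth, and matches how the fits
anchor each course's `a0` at its last pre-treatment observation.

## Key tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `sigma_i` | m^2 photon^-1 | 3.6e-24 | reference cold-adapted (2 degC) fit |
| `k_recinact` | s^-1 | 7e-5 | matches independent PsbA clearance rate |
| `ke_qp` | umol photons m^-2 s^-1 | 64 | low-light saturation of closure at 2 degC |
| `ke_npq`, `k_npq`, `k_npqslow` | umol m^-2 s^-1, s^-1, s^-1 | 49, 3e-3, 2e-6 | strong low-light NPQ induction |
| `kr_npq` | s^-1 | 3e-4 | minutes-scale NPQ relaxation |
| `active_t0`, `inactive_t0` | fmol (ug protein)^-1 | 42, 37 | ~50 % of PSII protein inactive at growth |
| `sigma_psii`, `rho` | A^2 quanta^-1, -- | 747, 0.3 | dark-acclimated induction fit |
| `tau1`, `tau2` | s | 8.4e-3, 5.8e-4 | slow electron transport at low temperature |
| `f0`, `fm` | relative | 0.41, 1 | FV/FM = 0.59 |
| noise CV | -- | 0.02 (fluorescence), 0.005 (O2) | small enough for recovery, nonzero to exercise fitting |

The defaults constitute one coherent reference parameter set — a
psychrophilic picoplankter at 2 degC — used as generating truth throughout
the tests and the acceptance benchmark.

## What the simulator emulates (and what it does not)

`simulate_time_course()` generates the latent state first (active
fraction, Y(NPQ), qP per interval) and then maps it to a self-consistent
set of fluorescence levels: the FM' quench ratio is solved (by `uniroot`,
tolerance 1e-12) so that the textbook definition `Y(NPQ) = FS/FM' - FS/FM`
reproduces the latent value, FS is positioned between F0' and FM' by the
latent qP, and all unquenched levels scale with the active fraction
(photoinactivated centres contribute no variable fluorescence). NPQ
downregulates `sigma_PSII'` and the antenna component of F0' by the same
factor — which is precisely the regime in which the
`F0'_Oxborough/sigma_PSII'` ratio is a robust proxy — so in a noiseless
simulation the proxy is exactly proportional to active PSII.
Photoinactivation raises the light-state F0' estimates (the 2-s-dark
measurements and hence the corrected F0' used for qP) in proportion to the
accumulated inactive fraction, but not the Oxborough estimator, mirroring
the include/exclude rationale for keeping both estimators. Under extreme
combined quenching and photoinactivation F0' is capped at 95 % of FM' to
keep the levels ordered (qP genuinely collapses there).

Observation noise is one multiplicative Gaussian error per FRR induction
per interval, shared by the levels extracted from that induction (the
dark-reference pair, the under-light triple, the 2-s-dark pair) and
independent across inductions and intervals. This reflects how those
levels arise — one curve fit per induction, sharing gain and positioning
error — and keeps the derived proxy and Y(NPQ) noisy at about the nominal
CV while preserving the physical ordering `F0' <= FS <= FM'`. Spectra
replicates vary by per-band amplitude jitter (pigment content differences
between independently grown cultures) plus small white instrument noise;
white noise is kept small because second differentiation amplifies it by
`sqrt(6)/h^2`.

The simulator does **not** emulate: electron-transport-chain state or
S-state cycling (beyond the 4-flashes-per-O2 stoichiometry), spectral
correction of cross sections, instrument drift or baseline wander,
photoacclimation of pigment content within a time course, or cell growth
during the 45-min treatment. Passing recovery tests therefore shows the
fitting machinery is unbiased under the stated noise model — not that real
instruments have no systematic errors.

## Numerical choices

* **Optimisers.** One-parameter fits (sigma_i, repair rates, ke_qp) use
  Brent's `optimize` on a bounded interval, with `sigma_i` rescaled to
  1e-24 units so the tolerance is meaningful; `fit_sigma_i` adds a short
  analytic-derivative Newton polish because Brent alone stops near
  sqrt(machine eps) relative. Multi-parameter fits (FRR induction,
  reopening, NPQ triple) use bounded L-BFGS-B with three-start multistart,
  keeping the best converged start; `rho` is bounded [0, 0.95]; rates at
  >= 0.
* **Degenerate inputs.** Zero-excitation or flat induction traces, flat
  time courses, constant reopening tails and zero-variance calibrations
  raise classed errors (`psiikinetics_degenerate_trace`,
  `psiikinetics_invalid_input`, `psiikinetics_fit_failure`) rather than
  returning numbers.
* **Tie-breaks.** Reopening lifetimes are reported sorted
  (`tau1` slow >= `tau2` fast). When one amplitude fraction is < 2 % or
  the two lifetimes coincide within 5 %, the fit collapses to a single
  slow phase with `fast_fraction = 0` and a warning — a deliberate
  convention so that single-phase data never silently return an arbitrary
  split.
* **FS bounds.** Measured FS slightly outside [F0', FM'] (within 2 % of
  the bound) is clipped with a warning; larger violations are errors.
* **Pooling and CIs.** Pooled fits share one kinetic parameter with
  per-course `a0` from each course's own t0 observation, unweighted least
  squares. CIs are nonparametric bootstrap percentiles over courses (1000
  resamples, seeded); with a single course the bootstrap resamples
  observations instead. The relaxation fit removes no slow-NPQ component
  first: over a 300-s recovery the zero-order contribution is orders of
  magnitude below the first-order relaxation.
* **Spectra.** Second derivatives are central differences on a linearly
  interpolated 2-nm grid with no smoothing. The chl-specific absorption
  coefficient uses the plain grid mean over 400-700 nm by default (a
  trapezoidal-integral option is exposed; they coincide on uniform
  grids). Band comparison uses pointwise Welch t-tests with raw and
  Holm-adjusted p-values; the significance mask uses the raw values, as
  pointwise significance is conventionally reported unadjusted. Welch's
  approximation runs slightly conservative at n = 3 replicates; the test
  suite verifies exact alpha-control at ample replication and bounded
  near-alpha behaviour at n = 3.

## Design choices that were genuinely open

* **Interface shape.** The package is a set of data-frame-first R
  functions plus `validate_config()`/`run_end_to_end()`; no shell
  front-end is shipped, since the intended users drive analyses from R
  scripts and the YAML-configured pipeline covers batch use.
* **Two F0' estimators kept.** The 2-s-corrected estimator (includes the
  photoinactivation F0 rise; used for qP) and the Oxborough estimator
  (excludes it; used for the activity proxy) serve different purposes and
  are both first-class outputs.
* **k_recinact fixed-input design.** `fit_krecinact` takes `sigma_i` and
  the pool ratio as inputs rather than co-fitting them: the target size is
  identified from +lincomycin courses and the pool ratio from protein
  data, and keeping them fixed mirrors that two-stage identification.
* **Units.** The proxy and calibration are treated as
  arbitrary-but-consistent: pooled fits accept any consistent active-PSII
  unit because `a0` is per-course. The Angstrom/metre and mole/photon
  conversions live in `psii_constants` only.

## Problem sizes

The test suite and the acceptance benchmark run 20-seed recovery studies
with 4 treatment lights and 6 x 300-s intervals per course, 40-flashlet
induction traces, and 300-replicate null simulations for the band
comparison — sizes chosen so each study's Monte Carlo error is well below
the tolerance it checks while the full suite stays in the minutes range.

## Known limitations

* The inactive-pool model treats `i0` as error-free; uncertainty in the
  protein-based pool estimate propagates directly into `k_recinact`.
* `ke_npq` and `k_npqslow` are weakly separable when only one treatment
  light is available; fits warn in that case, and pooled multi-light data
  are the supported design.
* The NPQ relaxation fit assumes the recovery-phase yield is a clean
  exponential; regulatory overshoots (rising Y(NPQ) in recovery) are
  flagged, not modelled.
* Calibration against oxygen flash yields inherits the optode's slope
  noise; with short dark phases the flash-yield x-values dominate the
  calibration scatter.
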