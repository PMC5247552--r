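# psiikinetics

Kinetic analysis of Photosystem II (PSII) photoinactivation, repair and
non-photochemical quenching (NPQ) from fast repetition rate (FRR)
chlorophyll fluorometry, with an oxygen flash-yield calibration of active
PSII content and second-derivative pigment spectroscopy. The package is
aimed at phytoplankton photophysiologists who run multi-light treatment
time courses (with or without the repair inhibitor lincomycin or the
xanthophyll-cycle inhibitor dithiothreitol) and want tested, reproducible
curve fitting for the full parameter set those experiments support — plus a
seeded forward simulator of every data type, so each fit can be validated
by parameter recovery against a known ground truth.

## The models

**Photoinactivation (target size).** With repair blocked, active PSII
decays with cumulative photon dose:

    A(t) = A0 · exp(−σi · E(I) · t),      k_pi = σi · E(I)

where σi (m² photon⁻¹) is the target size and E(I) the photon flux for
irradiance I. A single σi is fitted *pooled* across time courses at
different treatment lights.

**Damage–repair.** The classical two-state model assumes all PSII is
active at t₀ and solves dA/dt = −k_pi·A + k_rec·(A0 − A). Growing cells,
however, can carry a standing pool of photoinactivated-but-intact PSII
(estimated independently as the excess of immunoquantified PsbA protein
over oxygen-flash-yield counts of active centres, i0 = max(PsbA − A0, 0)).
The inactive-pool variant treats that pool as repair substrate from the
start:

    dA/dt = −k_pi·A + k_recinact·(A0 + i0 − A)
    A(t)  = T·r + (A0 − T·r)·e^(−(k_pi + k_recinact)·t),
            T = A0 + i0,  r = k_recinact/(k_pi + k_recinact)

Fitting the simple two-state model to data from cells with a genuine
inactive pool overestimates the repair rate constant several-fold; the
package demonstrates and tests exactly that bias.

**Quenching.** The open-PSII fraction follows a saturation law,
qP(I) = ke_qp/(ke_qp + I). Y(NPQ) induction combines a first-order
approach to a light-saturating amplitude with a slow zero-order phase in
cumulative illuminated time,

    Y(NPQ)(t) = I/(ke_npq + I) · (1 − e^(−k_npq·t)) + k_npqslow · t_cum

and relaxes first-order (kr_npq) after a drop to darkness or low light.

**FRR traces.** Flashlet inductions are fitted with the cumulative-closure
(Kolber-type) model with excitation connectivity ρ — yielding F0, FM,
σ_PSII and ρ — and the post-train reopening tail with a two-phase
exponential (lifetimes τ1 ≥ τ2). The ratio F0′_Oxborough/σ_PSII′ serves as
a rapid proxy for active PSII, calibrated by linear regression against
oxygen flash yields (4 flashes per O₂ per active centre).

All derived yields of standard quenching analysis are computed —
NPQ, Y(PSII), Y(NO), Y(NPQ), qP, FV/FM, both F0′ estimators, and the PSII
electron transport rate — with the exact partition
Y(PSII) + Y(NO) + Y(NPQ) = 1 enforced algebraically.

## Worked example

Simulate +lincomycin time courses at four treatment lights under the
default (cold-adapted, 2 °C) parameter set, derive the fluorescence proxy,
and recover the pooled target size:

```r
library(psiikinetics)
truth <- kinetic_ground_truth()          # sigma_i = 3.6e-24 m^2 photon^-1

courses <- dplyr::bind_rows(
  lapply(c(24, 97, 200, 400), function(L)
    simulate_time_course(truth, standard_light_program(L),
                         inhibitor = "lincomycin",
                         noise = noise_spec(0.02, seed = L),
                         sample_id = paste0("linco_", L)))
) |> derive_time_course()

fit <- fit_sigma_i(courses, n_boot = 200)
fit
#> <pooled_fit> model: target-size photoinactivation  ( 4 course(s) pooled )
#>   sigma_i      3.6013e-24  [95% CI 3.36466e-24, 3.66828e-24]
#>   residual SS = 1.241e-09 over 24 observations
```

The fitted target size, 3.60 × 10⁻²⁴ m² photon⁻¹, recovers the generating
value within 0.1 % and the bootstrap CI quantifies the spread across the
four pooled courses. A noisy FRR induction trace fits the same way:

```r
fit_frr_induction(simulate_frr_trace(truth, noise = noise_spec(0.02, seed = 1)))
#> <frr_fit> [dark-acclimated]
#>   f0 = 0.4038  fm = 1.002  sigma_psii = 709.2 A^2 quanta^-1  rho = 0.259
#>   rmse = 0.0146 over 40 flashlets
```

(A single 2 %-noise trace scatters around the generating σ_PSII = 747 Ų;
averaging over seeds converges on it.) Every fitted object supports
`tidy()`, `glance()` and `autoplot()`; `run_end_to_end()` drives the whole
chain (simulate → σi → repair → quenching → calibration → spectra) from a
YAML config and writes `fits.json`, `calibration.json` and spectra
comparisons.

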