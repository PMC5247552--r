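Package: psiikinetics
Title: Kinetics of Photosystem II Photoinactivation, Repair and
    Non-Photochemical Quenching from FRR Fluorometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse fast repetition rate (FRR)
    chlorophyll fluorometry experiments on marine phytoplankton. Provides a
    seeded forward simulator for flashlet induction traces, multi-light
    treatment time courses, oxygen-optode traces, PsbA protein decay series
    and whole-cell absorbance spectra; fitting of the cumulative-closure
    flashlet model (F0, FM, sigma_PSII, connectivity rho) and two-phase
    PSII reopening; derivation of quenching parameters (NPQ, Y(PSII),
    Y(NO), Y(NPQ), qP, two F0' estimators, PSII electron transport rate);
    pooled fitting of target-size photoinactivation, Kok damage-repair and
    an inactive-pool repair variant, qP light saturation, and NPQ
    induction and relaxation kinetics; oxygen flash-yield quantitation of
    active PSII with calibration of a fluorescence proxy; and
    second-derivative pigment-band spectroscopy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
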