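Package: alvosc
Title: Single-Compartment Modelling of Within-Breath Arterial Oxygen Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates within-breath alveolar and arterial oxygen tension
    oscillations during mechanical ventilation of the uninjured lung from a
    single alveolar compartment with constant oxygen uptake. Generates volume-
    and pressure-control ventilator waveforms from a resistance-compliance
    lung, predicts the rate of arterial oxygen decline during breath holds
    from lung volume, implements the measurement rules used on continuous
    intra-arterial oxygen traces (steady-state detection, two-minute
    oscillation statistics, steepest five-second decline with a 100 mmHg
    exclusion, Bland-Altman agreement), and performs quantitative computed
    tomography aeration analysis (Hounsfield-unit density classes, per-class
    tissue mass and gas volume). Includes seeded synthetic-data generators
    (noisy oxygen traces, breath-hold datasets, CT phantoms) so the whole
    pipeline can be exercised without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
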