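Package: breathEIT
Title: Breath-by-Breath Assessment of Acute Pulmonary Edema from EIT,
    Volumetric Capnography and Spirometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for breath-by-breath monitoring of acute pulmonary edema
    from three synchronized bedside modalities: electrical impedance
    tomography (EIT) pixel frames, volumetric capnography and spirometry.
    Implements breath segmentation from airway flow, apnea-based
    synchronization of the EIT and airway timebases, global and regional
    EIT variables (tidal impedance variation, end-expiratory lung
    impedance, center of ventilation, silent spaces, quartile band
    fractions), expirogram phase fitting with Bohr dead-space analysis,
    single-compartment respiratory mechanics, and per-breath
    mixed-effects comparison to baseline with Bonferroni correction.
    A parametric cohort simulator generates full virtual experiments
    (EIT frames, airway signals, event logs) under a configurable edema
    trajectory so every stage can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    pracma,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
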