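Package: nvcouple
Title: Neurovascular Coupling Analysis from Simulated MEG and Dual-Echo ASL
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying neurovascular
    coupling in the visual cortex with magnetoencephalography (MEG) and
    dual-echo pulsed arterial spin labeling (ASL) fMRI. Generates synthetic
    cohorts with known ground truth for a contrast-varying reversing
    checkerboard block design; localizes stimulus-induced gamma-band (30-80 Hz)
    power changes with an LCMV beamformer on a spherical conductor model;
    extracts peak gamma power via a Hilbert filter-bank time-frequency
    decomposition and visual-evoked-field peak latencies; separates BOLD and
    perfusion responses from dual-echo ASL series by surround averaging and a
    tag-control general linear model; quantifies baseline perfusion from
    multi-inversion-time ASL with a QUIPSS II kinetic model; and estimates
    per-subject neurovascular coupling slopes with exact Mann-Whitney,
    Holm-Bonferroni and Greenhouse-Geisser mixed-ANOVA group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
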