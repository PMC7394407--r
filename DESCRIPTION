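Package: posturadapt
Title: Cycle-by-Cycle Adaptation Analysis of Balance During Continuous
    Support-Surface Translations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the adaptation of human balancing
    behaviour during continuous sinusoidal antero-posterior translations of
    the support surface. Recordings of platform, head and pelvis
    antero-posterior displacement are segmented into perturbation cycles;
    per-cycle peak-to-peak displacement and mean position are extracted;
    their course across cycles is fitted with a three-parameter exponential
    (asymptote, intercept, time constant) from which an adaptation index is
    derived; head-pelvis coordination is measured as the lag-0
    cross-correlation per cycle and regressed against head displacement.
    Includes a synthetic trial generator with controllable adaptation
    envelopes and segment coordination for validation and parameter-recovery
    studies, plus an end-to-end cohort pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
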