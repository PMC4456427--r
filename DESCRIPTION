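Package: ecisr
Title: Analysis of Electric Cell-Substrate Impedance Sensing Wound-Healing Experiments
Version: 1.0.0
Authors@R:
    person("ECIS", "Maintainers", email = "maintainers@ecisr.example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of Electric Cell-substrate
    Impedance Sensing (ECIS) experiments on epithelial monolayers:
    multi-frequency impedance time-course I/O and channel extraction,
    the Giaever-Keese cell-covered microelectrode model and inversion for
    the cell-substrate adhesion parameter alpha, wound-healing sigmoid
    kinetics and migration rates, impedance-based attachment (adhesion)
    assays, moving-variance micromotion analysis, one-way ANOVA with
    Tukey-Kramer multiple comparisons, and a seeded simulator of complete
    ECIS wound-healing experiments for validation and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
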