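Package: tregswitch
Title: Population Dynamics, Spatial Fractal Metrics and Cohort Statistics
    for Treg Phenotypic Conversion Studies
Version: 0.1.0
Authors@R:
    person("Repro", "Engineering", email = "repro@example.org",
           role = c("aut", "cre"))
Description: Tools for analyses used to distinguish phenotypic conversion of
    naive CD4+ T cells into FOXP3+ regulatory T (Treg)-like cells from
    expansion of pre-existing Tregs. Implements three competing linear
    population-dynamics models (heritable acquisition, enhanced
    proliferation, reversible plasticity) with closed-form simulation,
    multi-start least-squares fitting and AIC model selection; box-counting
    fractal dimension and lacunarity of binary marker images with
    Mann-Whitney group comparison; flow-cytometry-style rectangular gating
    and fold-conversion statistics; a per-gene upregulated-cell-fraction
    statistic for single-cell count matrices; and synthetic-data generators
    for all of these input types so every analysis is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
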