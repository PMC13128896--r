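Package: methylwave
Title: Stratified Methylation Age Clock with Wave-Phase Discovery
Version: 0.1.0
Authors@R: person("Methylwave", "Developers", role = c("aut", "cre"),
    email = "maintainer@methylwave.dev")
Description: Tools for building and interrogating DNA methylation age
    clocks on Illumina EPIC-style beta-value matrices. Implements age- and
    sex-stratified Spearman feature selection, a seeded feed-forward
    neural-network age regressor with leave-one-cohort-out ensembling,
    expected-gradients (gradient SHAP) attribution aggregated into
    five-year age-bin profiles, Ward.D2 hierarchical clustering of age
    bins with multiscale-bootstrap AU/BP edge support, fixed-height phase
    cutting with sex-stratified comparison, and a calibration panel
    (MAE, RMSE, bias, slope/intercept, age-acceleration SD) for
    benchmarking clock predictions. Includes a seeded synthetic-methylome
    generator with planted age-trajectory CpG classes and phase
    boundaries, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
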