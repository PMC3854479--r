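Package: cascadevar
Title: Cell-to-Cell Variability in Protein Kinase Cascade Signaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic models of five-step protein kinase cascades and the
    cell-to-cell variability that arises when total kinase and phosphatase
    concentrations fluctuate between cells. Provides closed-form and
    semi-analytic steady-state evaluators for seven cascade variants (gradual,
    upstream/downstream negative feedback, distributed and single-step
    ultrasensitive switches, basal transcriptional feedback, coherent
    feedforward), a seeded log-normal cell-population generator with optional
    correlated or noise-free species, dose-response characterization (pathway
    sensitivity and maximal activation), population variability metrics
    (inter-quartile ratio, coefficient of variation) with closed-form
    log-normal counterparts, parameter sweeps, and linear stability analysis
    of steady states via numerical Jacobians.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
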