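Package: dnmrisk
Title: De Novo Mutation Based Prioritization of Risk Genes with
    Convergence Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes disease risk genes from trio de novo mutation (DNM)
    calls using the TADA-Denovo Bayesian model under multiple background
    mutation-rate models with a cross-model consensus rule, and supplies the
    downstream convergence analyses used in neurodevelopmental-disorder
    studies: co-expression and protein-interaction network connectivity with
    permutation tests, weighted co-expression module discovery via
    topological overlap with module eigengene trajectories over brain
    developmental periods, and Fisher-exact gene-set, intolerance
    (RVIS/pLI) and module mutation-class burden tests. Includes seeded
    synthetic-data generators for every input, with planted ground truth for
    calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
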