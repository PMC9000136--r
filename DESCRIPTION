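Package: gjcamp
Title: Multicellular cAMP/PKA/ERK Signaling with Regulated Gap-Junction Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates intracellular cAMP/PKA/ERK dynamics in epithelial
    monolayers in which optogenetically driven cAMP (bPAC) is exchanged
    between cells through gap junctions whose permeability is itself
    up-regulated by cAMP/PKA after a distributed (linear-chain) delay.
    Provides monolayer scenario builders (all-emitter, single- and
    small-emitter clusters), pharmacology mappings (IBMX, H89, ESI-09,
    carbenoxolone, Brefeldin-A, CX43-NGFP), pulse-response signal metrics
    (time-to-max, time-to-steady-state, overshoot ratio, undershoot depth),
    a shift/peak-normalization variability decomposition, paired one-tailed
    group comparisons, least-squares parameter fitting, and a synthetic
    single-cell ERK-KTR trace generator with expression heterogeneity and
    measurement noise.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
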