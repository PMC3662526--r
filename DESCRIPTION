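Package: fructansim
Title: Kinetic Simulation of Fructan Biosynthesis and Polymer Length
    Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic Michaelis-Menten reaction-network model of fructan
    (fructose polymer) biosynthesis in grasses. Builds the canonical
    14-species, 22-reaction network over glucose, fructose, sucrose and
    fructan oligomers (gf2..gf10, f2, f3), integrates it to steady state under
    a constant glucose supply, and predicts degree-of-polymerization (DP)
    distributions for DP 3-10. Includes velocity presets reproducing the
    classic 1-SST/1-FFT scheme and its variants, annotation of negative-mode
    LC-MS peak tables by DP via the [M-H]- m/z series, a seeded synthetic
    peak-table generator, and derivative-free fitting of reaction velocities
    to a target DP distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
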