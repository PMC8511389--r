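Package: canomix
Title: Individual-Based Canopy Simulation and Metamodel Analysis of Wheat Cultivar Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale individual-based simulator of winter wheat canopies with
    thermal-time development, layered diffuse-light competition over a periodic
    plot, and plastic tillering (probabilistic emergence, neighbourhood
    green-area-index cessation, intercepted-light regression), together with
    the in-silico experiment machinery for binary cultivar mixtures: the
    ref/diff mixture parameterization with seed-matched pure references and
    overyielding, maximin latin-hypercube experiment designs, a Kriging
    (Gaussian-process) emulator, variance-based Sobol sensitivity indices via
    the Jansen pick-freeze estimator, and Efficient Global Optimization with
    the Expected Improvement criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    parallel,
    lhs,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
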