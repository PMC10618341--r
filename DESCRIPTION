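Package: gpdVA
Title: Additive Genetic Variance Decomposition and Mating-Design Simulation
    under Gametic Phase Disequilibrium
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact conditional moments of the additive genetic variance of a
    population sample of fully homozygous lines, decomposed into the genic
    variance and the within- and between-chromosome gametic phase
    disequilibrium (GPD) covariance components, treated as Gaussian quadratic
    forms in the QTL effects. Includes an in-silico breeding simulator
    (disjoint, factorial and half-diallel mating designs, Haldane meiosis,
    doubled-haploid derivation, random intermating), a calibrated synthetic
    founder-panel generator, and the finite-population regression describing
    the per-generation decay of the between-chromosome disequilibrium
    variance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Genetics, QuantitativeGenetics, Breeding, Simulation
RoxygenNote: 7.3.3
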