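Package: cellulosim
Title: Stochastic Molecular Simulation of Enzymatic Cellulose Hydrolysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds in-silico cellulose substrates (microfibrils of 36-chain
    elementary fibrils with banded crystalline and amorphous regions) and
    simulates their enzymatic depolymerization with a per-minute Monte Carlo
    engine. Endoglucanases, cellobiohydrolases (I and II, processive and
    non-processive) and beta-glucosidase are represented with class-specific
    binding rules, surface accessibility, processivity, desorption and
    counter-based product (glucose/cellobiose) inhibition. Observables include
    soluble sugar concentrations, cellulose conversion, hydrolysis rates,
    chain-length distributions, crystallinity trajectories and degrees of
    synergism between enzymes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
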