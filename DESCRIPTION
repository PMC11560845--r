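Package: endosim
Title: Vertical-Transmission Dynamics of Induced Fungal Endosymbioses
Version: 0.1.0
Authors@R:
    person("endosim", "maintainers", email = "endosim@example.org",
           role = c("aut", "cre"))
Description: Models and analyses the population dynamics of a bacterial
    endosymbiont vertically transmitted through the asexual spores of a
    filamentous fungus. Provides the fitness index of an endosymbiosis
    (positive fraction times germination success), a discrete-generation
    recursion for the bacteria-positive spore fraction under propagation
    without selection together with its fixed points, decline factor and
    wash-out round, a seedable finite-population simulator of the
    FACS-based serial-passage selection experiment, estimators that turn
    round-by-round count data into model parameters with confidence
    intervals, exact and approximate significance tests, an allele
    frequency sweep filter, voxel-based quantification of intracellular
    bacterial load from 3D fluorescence stacks, and a synthetic-data
    generator that emulates the full experimental design so every stage
    is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
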