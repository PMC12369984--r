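Package: mesoinvasion
Title: Mesoscale Phenotype-Switching Dynamics of Tumor-Spheroid Invasion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing and modeling the mesoscale dynamics of cancer
    cells disseminating from tumor spheroids into three-dimensional collagen
    matrices. Implements a continuous-time Markov model of migration-phenotype
    switching among blebbing (BB), actin-enriched pseudopodial (AE),
    lamellipodial (LA) and filopodial (FP) states, with optional space-time
    modulation of transitions into the filopodial state near the spheroid
    boundary; an agent-based simulator of radial cell trajectories with
    phenotype-dependent Gaussian steps; estimators for transition-rate
    matrices, step statistics, radial density profiles, spatial enrichment
    fields, and filopodial-depletion statistics from cell-tracking tables; a
    coupled advection-reaction continuum solver for the four phenotype density
    profiles; and pore-size estimation from binarized matrix images by the
    maximal-inscribed-disk method.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
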