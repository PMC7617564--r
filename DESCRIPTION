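Package: vsaslkin
Title: Kinetic Modelling of Velocity-Selective ASL Perfusion Data
Version: 0.1.0
Authors@R:
    person("VSASL", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward kinetic modelling and voxelwise multi-start fitting of
    velocity-selective arterial spin labelling (VSASL) difference signals
    acquired at multiple label-to-crusher times (LCT). Estimates cerebral
    blood flow, bolus duration and a residual macrovascular component per
    voxel, aggregates parameter maps over atlas regions, computes
    cerebrovascular reactivity (CVR) from two-condition (normocapnia /
    hypercapnia) acquisitions, and reproduces the truncated-LCT
    identifiability experiment. Includes a multi-subject synthetic phantom
    generator so the whole pipeline is testable without acquired data, a
    noncentral-t power calculator for paired designs, a minimal NIfTI-1
    reader/writer, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
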