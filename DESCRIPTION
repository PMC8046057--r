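Package: dentomorph
Title: Micro-CT Densitometry and Morphometry of Primary Teeth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative micro-computed-tomography and histomorphometry toolkit
    for dental hard tissues. Fits hydroxyapatite density calibrations from
    multi-rod standards, segments enamel, dentin, acellular cementum and
    hypomineralized interglobular dentin by density windows (including the
    median-filter-and-mask-back cementum procedure), constructs anatomical
    regions of interest anchored at the cementum-enamel junction, measures
    tissue densities, maximal-inscribed-sphere local thickness, interglobular
    dentin volume and crown length, and summarizes case cohorts against
    control-derived 95% confidence bands. Ships a synthetic tooth-phantom
    generator with voxel-level ground truth so every stage is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
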