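Package: blastopol
Title: Apical-Domain Detection and Polarization-Timing Analysis for
    Cleavage-Stage Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for asynchronous blastomere polarization
    in 8-cell mouse embryos. Detects apical domains from cortical intensity
    profiles using a three-criterion rule (arc-length fraction, cortical
    intensity ratio, z-depth), classifies blastomeres as early- or
    late-polarizing relative to compaction (inter-blastomere angle threshold),
    measures cell geometry (contact angles, apex geometry, 3D aspect ratios),
    and computes the division-symmetry and trophectoderm-fate contingency
    statistics that link early polarization to lineage bias. Includes a seeded
    synthetic time-lapse embryo generator that provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tiff,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
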