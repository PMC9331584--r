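Package: earmetrics
Title: Maize Ear Phenotyping from Multi-View Grain Instance Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the spatial organization of maize ears from
    multi-view images acquired on motorized rollers. From per-view binary ear
    masks and labeled grain instance masks, the package extracts ear length
    along the central axis, per-pixel diameter profiles, grain dimensions with
    a cylindrical arc-length correction, cohort (ring) structure, composite
    grain-number estimates, grain-set-ratio profiles, and fertile/aborted zone
    lengths, and clusters ears by their length-normalized abortion profiles.
    A rolling-contact model of the roller acquisition geometry predicts the
    cumulative circumference coverage of a view series, and a parametric
    synthetic ear generator renders multi-view masks with exhaustive ground
    truth so the whole pipeline can be exercised without real images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    tiff,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
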