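Package: mitodiv
Title: Tracking Overlapping Nuclei and Measuring Division Angles in
    Micropattern Time-Lapse Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts, localizes and tracks overlapping cell nuclei in
    fluorescence time-lapse videos of micropatterned cell clusters by
    fitting competing penalized two- and three-component Gaussian mixture
    image models to every frame with Powell's derivative-free method.
    Detects the exact frame of the two-to-three-cell transition from the
    product of the time derivatives of three fit-derived features, and
    measures the division angle of the new daughter pair relative to the
    axis of the two pre-existing cells.  Includes extraction of
    single-cluster sub-videos from full-field acquisitions, a seeded
    synthetic-video generator with ground truth, batch processing, and a
    Kolmogorov-Smirnov utility for comparing angle distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
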