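Package: fibromorph
Title: Morphometry of Liver Microvasculature in Micro-CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies fibrotic remodelling of the hepatic sinusoid network in
    high-resolution micro-CT volumes. Provides a synthetic phantom generator for
    vascular networks with known ground truth, an intensity preprocessing chain
    (block binning, linear bias-field correction, bright-artifact suppression,
    robust normalization), a transparent rules-based segmenter for sinusoid,
    vessel and lesion classes, exact 3D morphometry (local thickness by largest
    inscribed sphere, region-restricted volume proportions), and the
    multi-group statistics used to compare disease stages (Kruskal-Wallis with
    Dunn post hoc, Dunnett many-to-one tests, two-way ANOVA with an
    interaction-triggered one-way fallback).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    RNifti,
    EBImage,
    multcomp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
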