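Package: sibav
Title: Hybrid Audio-Visual Feature Analysis of Sibilant Articulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the place of articulation of the sibilants
    /s/ and /sh/ from synchronized audio recordings and articulator
    segmentation masks. Provides a synthetic multimodal cohort simulator,
    a 76-feature acoustic battery (time-domain, full-band spectral and
    frication noise-band descriptors), an 87-feature-per-camera visual
    battery (radiomics-style texture families GLCM, GLRLM, GLSZM and NGTDM
    plus articulator shape descriptors), per-speaker feature aggregation
    with end-cropping, and a non-parametric statistical battery
    (Mann-Whitney U with rank-biserial correlation, Kruskal-Wallis with
    eta-squared, Bonferroni post hoc tests, variance-ratio screening) that
    ranks features by effect size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    jsonlite
Config/testthat/edition: 3
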