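Package: adipo3d
Title: Three-Dimensional Adipocyte Morphometry in Cleared Adipose Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies adipocyte size and shape in two-channel 3D fluorescence
    stacks of cleared adipose tissue and in extracted-cell preparations.
    Provides a synthetic tissue generator (lognormal cell size distributions,
    ball-clipped Laguerre packing of in situ depots, sparse sphere packing of
    ex situ extracts, exponential depth attenuation), a classical seeded
    watershed segmenter for lipid/extracellular-matrix channel stacks, per-cell
    morphometry (volume, Crofton surface area, equivalent spherical diameter,
    sphericity, border contact), the mask quality-control filters used for
    confocal adipose stacks (border, minimum voxel volume, minimum sphericity),
    and distribution statistics: kernel density estimates, a permutation
    two-sample Kolmogorov-Smirnov test with the Phipson-Smyth p-value
    estimator, and a linear model for depot, sex and body-weight effects on
    per-sample morphometry summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
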