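Package: graintex
Title: Grain-Coat Texture Phenotyping from Seed Plate Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts second-order texture descriptors (gray-level
    co-occurrence and run-length matrix features, accumulated
    omnidirectionally over all eight pixel neighbour offsets) and
    color-space means from segmented images of cereal grains on a white
    background, and runs the downstream statistics used in seed
    phenotyping studies: trait-similarity clustering (UPGMA on
    correlation distance), correlation-matrix PCA, one-way ANOVA factor
    contributions, year-trend tests with permutation and bootstrap null
    bands, and germination-association tests.  A synthetic plate and
    multi-year panel generator with known ground truth makes every stage
    testable without photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    png,
    yaml,
    jsonlite,
    ape,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
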