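Package: cytoprofile
Title: Cytological Profiling and Mode-of-Action Assignment for High-Content Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for image-based cytological profiling of multiwell
    high-content screens. Simulates 384-well screens with known phenotype
    ground truth, segments nuclei and extracts per-cell compartmental
    features from fluorescence images, aggregates cells to
    control-normalized feature profiles scored between -1 and 1, clusters
    profiles against an annotated reference-compound library to predict
    modes of action, and computes cytotoxicity, DNA-content cell-cycle and
    fold-change endpoints with Student's t statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    EBImage,
    jsonlite,
    pheatmap,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ape,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
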