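Package: hatchplot
Title: Colorblind-Accessible Scatter Plots with Redundant Color and Hatch Coding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Creates accessible scatter plots of single-cell embeddings
    (UMAP, tSNE, PCA) and in-situ spatial data by redundantly coding point
    groups with both color and hatch patterns, so group identity survives
    loss of the color channel. Each group's points are partitioned into
    dense clusters, which receive coarse region hatching, and sparse
    singletons, which receive per-marker pattern glyphs. Includes a
    colorblind-friendly 40-color default palette, a pattern grammar for
    custom line-based patterns, color-vision-deficiency simulation for
    auditing palettes and rendered figures, deterministic SVG/PNG/PDF
    export, synthetic data generators for embedding-like and tiled spatial
    point mixtures, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    farver,
    ggplot2,
    grDevices,
    igraph,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    colorspace,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
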