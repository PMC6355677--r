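Package: phenovol
Title: Digital Biovolume and Water-Use-Efficiency Phenotyping from Multi-View RGB Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for image-based plant phenotyping in
    greenhouse pot experiments. Segments plants from three orthogonal RGB
    views (excess-green index with Otsu or fixed thresholding), computes the
    pixel-based Digital Biovolume trait and its treated-to-control ratio,
    reconstructs per-pot water budgets from gravimetric weighing logs
    (bare-soil evaporation correction, cumulative transpiration) to estimate
    Water Use Efficiency and its drought-to-control ratio with heatmap
    classification, and applies the associated statistical layer: per-day
    two-way genotype-by-treatment ANOVA, one-way ANOVA with Duncan's new
    multiple range test, and linear correlation of digital against manual
    biomass. A seeded synthetic-experiment generator emulates wheat
    drought-screening and tomato biostimulant trial designs, producing
    growth trajectories, pot-weight logs and renderable plant images with
    ground-truth masks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    pheatmap,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
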