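Package: crownepf
Title: Spectral-Spatial Classification of UAV Hyperspectral Imagery with
    Edge-Preserving Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pixel-wise support vector machine classification of
    hyperspectral reflectance cubes with Gaussian radial-basis kernels,
    followed by spatial regularization of the per-class probability maps
    with edge-preserving filters (joint bilateral filter and guided
    filter) driven by a co-registered guidance image, maximum-probability
    fusion, and accuracy assessment (overall accuracy, Cohen's kappa,
    per-class producer accuracy, mean structural similarity). Designed
    for extracting crowns of pest-damaged conifers from UAV imagery, and
    ships a synthetic-scene generator with known ground truth for
    end-to-end validation. Reads and writes ENVI, TIFF, PNG and CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
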