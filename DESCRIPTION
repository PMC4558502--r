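Package: ncscreen
Title: Nuclear-Cytoplasmic Translocation Analysis for High-Content RNAi Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for image-based RNAi screens that read out the
    nuclear-cytoplasmic translocation of a shuttling protein (such as hnRNP A1
    under hypertonic stress). Segments nuclei from a nuclear-stain channel,
    builds per-cell cytoplasmic ring masks by exact Euclidean distance
    geometry, computes per-cell nuclear/cytoplasmic mean-intensity ratios,
    aggregates cells to wells, scores assay quality with the Z'-factor,
    calls hits at mean + 3 sigma with replicate concordance, and monitors
    transfection with death-siRNA cell counts. Ships a seeded synthetic
    two-channel plate simulator with per-cell ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    tiff,
    yaml,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
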