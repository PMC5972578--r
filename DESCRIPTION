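Package: endograd
Title: Protein Distribution Gradients in Stained Grain Endosperm Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies gradients in storage-protein distribution across the
    wheat grain endosperm from light-microscopy sections stained with Naphthol
    Blue Black. Pixels are classified as protein or background by supervised
    maximum-likelihood (Gaussian) classification with replicated training
    samples; concentric equal-width zones are rendered inward from a manually
    drawn endosperm outline using the Euclidean distance transform; per-zone
    by-area protein concentrations are calibrated against grain nitrogen
    measurements; individual protein bodies are extracted as 8-connected
    components and their areas and shortest distances to the outline measured.
    Fixed-effects linear trends of concentration and log body size against
    distance from the aleurone layer are fitted, with a distance-squared
    lack-of-fit check. A synthetic section generator with exact ground truth
    supports validation of every stage, and small experiment-design utilities
    compute thermal-time-equivalent sampling days and nutrient-solution
    nitrogen supply.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    igraph,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    mgcv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
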