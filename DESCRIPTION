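Package: renomorph
Title: Whole-Slide Image Morphometry of Renal Fibrosis, Epithelial Mass,
    and Microvascularity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Positive-pixel-count quantification of chromogenic stains
    (Masson trichrome, periodic acid-Schiff, DAB immunohistochemistry) on
    brightfield histology region exports, stratified by renal anatomic
    compartment (cortex, medullary outer and inner stripe).  Includes
    hue-saturation-intensity pixel classification with circular-hue stain
    profiles, the trichrome-minus-PAS fibrosis statistic, microvessel
    density and area measurement on CD34-style images, a digital-ruler
    stripe-width measurement, cohort summary and pairwise-correlation
    reporting with hierarchical variable clustering, and a synthetic
    stained-tissue and cohort generator with exact pixel ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
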