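Package: finprint
Title: Photo-Identification of Individual Fish from Skin Dot Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic photo-identification of individual fish from the
    melanophore dot pattern on their skin, after the workflow used for
    Atlantic salmon (Salmo salar): landmark-based extraction of a standardized
    skin region of interest, dot localization with a small convolutional patch
    classifier (or a deterministic blob detector), trimmed nearest-neighbour
    pattern matching under an exhaustive translation search,
    representative-pattern enrollment for long-term identification, and a
    histogram-of-oriented-gradients template-scanning alternative. Includes a
    seeded synthetic fish-image generator emulating the acquisition conditions
    (green background, lateral view, in-plane rotation, illumination change,
    growth between sessions) so the whole pipeline can be exercised and
    validated without access to real images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
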