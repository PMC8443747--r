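Package: mn3d
Title: Three-Dimensional Quantification of Micronuclei in Multi-Channel
    Fluorescence Z-Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Counts nuclei and micronuclei in confocal fluorescence Z-stacks
    by true three-dimensional reconstruction, so that grazing optical sections
    of a regular nucleus are not mistaken for micronuclei. Provides per-channel
    bilateral smoothing, locally adaptive discriminant (Otsu) thresholding,
    morphological clean-up, 3D connected-component labelling, equivalent-radius
    morphometry, size-band classification, multi-channel overlap-rate
    classification of objective nuclei and nuclear-envelope status, and
    ellipse-fitting separation of fused nuclei.  Includes a seedable phantom
    generator with ground truth, a reproducible label-edit script mechanism,
    TIFF/CSV input-output, and a command-line driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    tiff,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
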