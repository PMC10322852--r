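Package: cryosect
Title: Optimal Slice Thickness Modelling for Block-Face Cryo-Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the detectability of point-like fluorescent cells under
    block-face cryo-imaging, where subsurface signal is attenuated
    exponentially with depth (Beer-Lambert). Provides the closed-form optimal
    slice thickness and optimal cell intensity, piecewise
    sensitivity-vs-thickness relationships and the under-sampling correction
    factor; digital sectioning simulators on virtual tissue volumes
    (compliant, perturbed and overlapping placements); a synthetic block-face
    image-stack renderer; and a section-and-image resampling pipeline with
    threshold plus 3D connected-component cell counting and attenuation /
    intensity parameter estimation from decay profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
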