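Package: critfocus
Title: Critical-Illumination Autofocus for Sequencing Microscopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based defocus estimation for fluorescence microscopes that
    use a square critical-illumination excitation field. The reflected field's
    conjugate image shrinks or grows linearly with defocus; the separation
    between the sub-pixel positions of the rising and falling edge-gradient
    extrema is a linear, shift- and intensity-immune defocus metric. The
    package provides a seeded synthetic optics simulator for defocused field
    images, 1-D profile and gradient operators, sub-pixel edge-pair
    localization, calibration of the standard evaluation curve (slope,
    reference separation, R-squared, sensitivity), single-shot and multi-frame
    defocus estimation, and a closed-loop iterative focusing protocol against
    a virtual quantized stage, together with TIFF/CSV/JSON/YAML interchange
    and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
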