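Package: fundusnc
Title: Retinal Fundus Image Enhancement by Normalized Convolution with a
    Domain Transform
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Enhancement of color retinal fundus photographs by background
    suppression. A smooth background image is estimated with normalized
    convolution using a domain-transform box kernel, fused with the
    original image to amplify vessel contrast, and denoised in two stages
    (fourth-order PDE diffusion followed by a relaxed median filter).
    Includes objective quality metrics (contrast improvement index over
    vessel masks, linear index of fuzziness), a seeded generator of
    fundus-like phantoms with ground-truth vessel and field-of-view
    masks, readers for DRIVE-style dataset layouts, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
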