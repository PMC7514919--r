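Package: qsigmoid
Title: Q-Sigmoid Intensity Transforms for Region-of-Interest Enhancement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bell-shaped sigmoid and q-sigmoid grayscale intensity
    transforms built on the Tsallis q-exponential, for highlighting a
    target intensity band in 2-D images such as breast ultrasound scans.
    Provides the transform family and its analytic calculus (derivatives,
    one-sided limits, Taylor-ratio and difference-quotient diagnostics),
    classical comparison enhancers (histogram equalization, gray-level
    slicing, Otsu thresholding), evaluation statistics (convex-hull region
    error, absolute mean brightness error, a dilation-ring segmentation
    similarity), seeded synthetic phantom and speckled-lesion generators,
    and reproducible experiment runners with PNG/TIFF input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
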