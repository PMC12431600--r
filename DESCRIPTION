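Package: vibrofruit
Title: Image-Based Vibration Analysis for Non-Destructive Fruit Firmness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for predicting fruit firmness from image-based vibration
    response. Simulates vibrating-fruit displacement signals and rendered
    frame sequences, tracks the fruit surface centre with sub-pixel
    precision, extracts the damping ratio (logarithmic decrement) and
    natural frequency (FFT magnitude-spectrum peak), and maps both features
    to firmness with a small feed-forward network trained by
    Levenberg-Marquardt. Includes regression metrics, residual diagnostics,
    bootstrap percentile prediction intervals and paired-t comparison for
    model evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    e1071,
    jsonlite,
    pracma,
    png,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
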