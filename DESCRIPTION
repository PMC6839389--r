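Package: sonodct
Title: Frequency-Domain Computer-Aided Diagnosis of High-Frequency Skin Sonograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for frequency-domain analysis of high-frequency (50 MHz)
    skin ultrasound. Converts raw radio-frequency (RF) scans to B-mode
    intensity images, computes the orthonormal two-dimensional discrete
    cosine transform (DCT), extracts whole-image spectral features as the
    singular values of the log-absolute DCT, classifies sonograms with a
    shallow pattern-recognition network trained by scaled conjugate
    gradient backpropagation, and segments sonograms into healthy and
    suspicious tissue by thresholding per-block mean DCT magnitudes with
    Otsu's adaptive method. Includes a synthetic sonogram phantom
    generator with pixel-level ground-truth lesion masks so every
    pipeline is testable without clinical data, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    grDevices,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
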