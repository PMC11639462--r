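Package: aviscan
Title: Small-Object Bird Detection Toolkit with Composable Network Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Composable building blocks for small-object bird detection in
    surveillance imagery: a receptive-field attention convolution, a
    multi-scale fusion neck with dynamic upsampling, Gaussian scale-sequence
    fusion and an added high-resolution detection level, a lightweight shared
    detail-enhanced detection head, and the Inner-ShapeIoU family of
    bounding-box regression losses. Includes a tape-based autodiff engine
    with compiled convolution kernels, a synthetic wetland-scene generator
    producing YOLO-format datasets, detection evaluation (precision, recall,
    mAP, confusion matrix), and parameter/FLOP accounting for model variants.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
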