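Package: fundusdr
Title: Fundus Image Enhancement and Diabetic Retinopathy Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contrast enhancement and severity grading of retinal
    fundus images in diabetic retinopathy screening. Implements an
    incomplete-beta intensity transform whose shape parameters are selected
    per image by an artificial bee colony maximising an edge/entropy/contrast
    fitness, a suite of image quality measures (entropy, PSNR, SSIM, GMSD,
    PCQI), class-balancing augmentation and stratified splitting, a compact
    residual network with a trainable TOP-Q weighted pooling layer, a
    bounded piecewise-linear activation and a branch-usage balance loss, a
    multiclass linear SVM head trained by subgradient descent, per-class
    evaluation metrics, and a seeded generator of synthetic graded fundus
    images so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
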