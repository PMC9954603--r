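Package: gliowave
Title: Haar Wavelet Features for Binary Brain-MRI Tumor Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for binary glioma-versus-rest classification of axial
    T2-weighted brain MRI slices using multilevel 2D Haar discrete wavelet
    transform (DWT) sub-band features. Provides a seeded synthetic brain
    phantom generator with controllable lesions and skull ring, skull
    stripping and intensity preprocessing, an exact unnormalized 2D Haar
    DWT with perfect reconstruction and feature-tensor assembly, faithful
    builders and structural audits for two convolutional network
    architectures together with a small CPU training engine, a kernel SVM
    baseline with grid search, the standard confusion-matrix metric suite,
    and paired-classifier comparison statistics (Pearson chi-squared,
    Edwards-corrected McNemar, exact binomial).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    e1071,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti,
    optparse
Config/testthat/edition: 3
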