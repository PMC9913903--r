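Package: fmlda
Title: Fuzzy Maximum-Uncertainty Linear Discriminant Analysis for NIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and classification of high-dimensional,
    small-sample near-infrared (NIR) absorbance spectra. Implements maximum
    uncertainty linear discriminant analysis (MLDA), its fuzzy extension
    built on fuzzy c-means cluster centers (FMLDA), and direct LDA (DLDA),
    together with standard normal variate (SNV) preprocessing, a
    deterministic k-nearest-neighbour classifier, stratified train/test
    splitting, a synthetic NIR spectra generator, and a grid-search
    experiment driver. The discriminant fits handle the d >> n regime
    directly, without a PCA pre-step, via eigenvalue shrinkage of the
    pooled within-class scatter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), withr, class, optparse, yaml, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
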