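Package: aplScreen
Title: Early Screening of Acute Promyelocytic Leukemia from Stained Blood Smears
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A three-stage pipeline for morphology-based early screening of
    acute promyelocytic leukemia (APL) in peripheral blood smear microscopy.
    Stage one locates leukocytes by Reinhard-style color normalization,
    methylene-blue/eosin color deconvolution under the Beer-Lambert model,
    Otsu binarization and connected-component bounding boxes. Stage two
    classifies fixed-size cell crops into six leukocyte classes with a compact
    squeeze-and-excitation convolutional network implemented natively
    (float32 im2col/BLAS engine), including exact parameter and
    multiply-accumulate accounting and the ablation variants. Stage three
    turns cell counts and a CBC panel into a Sanz/PETHEMA-GIMEMA risk level
    and an advisory diagnostic opinion. A synthetic Romanowsky-type smear
    generator with ground-truth boxes and class-discriminative cell renderings
    makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
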