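Package: opcnn
Title: Outer-Product Convolutional Networks for Bimodal Drug Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multimodal fusion classifiers for predicting clinical-trial
    outcomes of drug candidates from a bimodal feature table (chemical
    descriptors and target-based properties). Implements the outer-product
    convolutional neural network (OPCNN), which feeds the augmented outer
    product of two modality embeddings into a two-dimensional residual CNN,
    together with a family of deep multimodal networks covering early,
    intermediate, and late fusion with addition, product, concatenation,
    tensor-fusion-layer, and multimodal-circulant-fusion operators. Includes
    class-imbalance strategies (cost-sensitive binary cross-entropy, SMOTE,
    and their hybrid), an evaluation suite centred on the Matthews
    correlation coefficient, a repeated stratified cross-validation
    benchmark harness with two-sided t-test comparisons, and a synthetic
    bimodal data generator whose labels depend on a cross-modality
    interaction. The neural-network core (dense, convolutional, and fusion
    layers with Adam optimisation) is implemented in R and C++ via
    'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    optparse,
    e1071,
    randomForest
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
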