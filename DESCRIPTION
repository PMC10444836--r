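Package: toposdm
Title: Fine-Scale Species Distribution Modelling from Topographic Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling the fine-scale distribution of plants over
    terrain: derivation of topographic predictors (slope, aspect, profile
    curvature) from a digital elevation model, collinearity screening by
    variance inflation factors, seven species distribution modelling
    algorithms behind one fitting interface (BIOCLIM envelope, Domain/Gower
    similarity, Mahalanobis distance, GLM, GAM, random forest, support
    vector machine), repeated cross-validated evaluation by ROC/AUC and
    sensitivity/specificity, habitat-suitability mapping with three-band
    classification, and a virtual-species simulator for end-to-end
    validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    mgcv,
    randomForest,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
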