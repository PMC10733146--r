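Package: drpscreen
Title: Ex Vivo Drug Response Profiling for Hematologic Malignancies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for plate-based ex vivo drug response
    profiling (DRP) of primary tumor cells: 384-well plate data models,
    DMSO-control viability normalization and quality control, trapezoidal
    AUC/VUC dose-response summarization and five-parameter logistic curve
    fits, association of ex vivo responses with in vivo response groups,
    elastic-net logistic stability selection over repeated cross-validation
    splits, event-free survival modelling (Kaplan-Meier, Cox regression,
    maximally selected log-rank cutpoints), and a synthetic-data generator
    that emulates the screening design with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    glmnet,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
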