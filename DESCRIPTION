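Package: qcla
Title: Question-Based Computational Language Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying open-ended word responses to mental-health
    questions with word embeddings. Builds and loads semantic spaces
    (co-occurrence plus singular value decomposition), scores responses
    against empirically collected word norms (unipolar and bipolar semantic
    similarity scales), trains cross-validated ridge regression models
    mapping embeddings to rating-scale items and to lexicon valence ratings,
    computes item-level psychometrics (descriptives, Cronbach's alpha,
    McDonald's omega, correlations and partial correlations controlling for
    predicted valence), and places individual words on supervised dimension
    projections with permutation p-values and false-discovery-rate control.
    Includes a synthetic-cohort generator with planted latent severity so the
    full pipeline can be exercised and validated without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
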