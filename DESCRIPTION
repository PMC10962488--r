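Package: denovomol
Title: Property-Conditioned De Novo Molecular Generation with Partition
    Transfer Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for de novo design of drug-efficacious small molecules from
    SMILES corpora. Implements a property-conditioned variational autoencoder
    whose latent space is reweighted by a feature-property-correlation (FPC)
    attention network, partition transfer learning (PTL) and its recurrent
    variant (PRTL) onto QED-by-activity sub-domains of an activity dataset,
    fingerprint-based activity prediction models with feature selection and
    cross-validated hyperparameter search, the standard generation-quality
    metric suite (validity, uniqueness, drug-likeness, lead and novelty rates),
    chemical-space embedding, synthetic-accessibility scoring, and a screening
    stage that ranks candidates by predicted potency or docking score and picks
    synthesis candidates by SA score. A deterministic fragment-grammar
    simulator provides valid SMILES corpora and activity datasets with known
    structure-activity signal so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    e1071,
    glmnet,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
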