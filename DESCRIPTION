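Package: SpectraForest
Title: Classification of UV-Vis Absorption Spectrum Features Related to
    Photoreactive Potential
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for photosafety-oriented classification of organic
    molecules from their UV-Vis absorption behaviour. Molecules are labelled
    photoreactive-potential positive when an experimental absorption maximum
    falls between 290 and 700 nm with a molar extinction coefficient of at
    least 1000 L/mol/cm (the ICH S10 criterion), and random-forest models are
    trained to predict that spectrum class directly from the 2D structure
    using circular fingerprints, MACCS keys and modified-distance atom-pair
    descriptors. Includes structure curation (standardization, eligibility
    filtering, duplicate removal), descriptor calculation, model training and
    validation (out-of-bag estimation, Y-scrambling, feature selection),
    statistical evaluation (sensitivity, specificity, accuracy, Matthews
    correlation, ROC), triage of high-confidence misclassifications by
    Tanimoto similarity and peak-list quality heuristics, cross-tabulation of
    the spectrum class against 3T3 NRU in vitro phototoxicity outcomes, and a
    seeded synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    ChemmineR,
    ChemmineOB,
    randomForest,
    rpart,
    e1071,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
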