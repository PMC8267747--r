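Package: arbind
Title: Consensus Classification of Androgen-Receptor Binding from Docking
    Scores and Chemical Fingerprints
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits and applies consensus classifiers for androgen-receptor
    (AR) binding on strongly imbalanced screening data. Combines a docking
    score threshold, Tanimoto distances between binary molecular
    fingerprints averaged over reference panels of known binders and
    non-binders, class-conditional Gaussian ("naive Bayesian") models of
    docking scores, and multivariate logistic regression fitted by maximum
    likelihood, arranged into thirteen single and cascade/consensus
    classification procedures. Includes the full imbalanced-classification
    metrics suite (sensitivity, specificity, accuracy, MCC, PPV, NPV,
    likelihood ratios, balanced classification rate, rank-based ROC AUC), a
    seeded synthetic-data generator with zero-inflated docking scores and
    class-structured fingerprints, a pre-trained reference model, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
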