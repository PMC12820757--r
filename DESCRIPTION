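Package: quantdesc
Title: Hybrid Quantum-Mechanical Molecular Descriptors for Property Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds hybrid molecular representations that concatenate
    geometric descriptors (Coulomb matrix, Bag-of-Bonds, SLATM spectra) with
    an electronic descriptor assembled from semi-empirical tight-binding
    properties (energies, frontier orbital eigenvalues, Mulliken charges),
    and trains two regression engines on them: kernel ridge regression with
    joint split/hyperparameter optimisation and a reference second-order
    gradient-boosted tree learner. Includes conformer-ensemble curation
    (Kabsch RMSD, energy windows, RMSD hierarchical clustering), farthest
    point sampling, delta learning, learning-curve and residual evaluation,
    exact Shapley feature attribution, and a synthetic-data generator that
    emulates tight-binding property records with controlled correlation
    structure so the whole pipeline is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    xgboost,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
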