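Package: prbind
Title: Protein-RNA Binding Affinity Prediction with Gradient Boosted
    Regression Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the dissociation free energy (deltaG) of protein-RNA
    complexes from sequence- and structure-derived features. Parses PDB
    complexes, DSSP secondary-structure output, RNAfold partition-function
    output and RNAVIEW base-pair annotations; computes a catalogue of
    physicochemical protein features and RNA sequence/ensemble/base-pair
    features; classifies complexes into six groups by RNA type; and trains
    per-class gradient boosted regression tree models with greedy forward
    feature selection under leave-one-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    optparse
Config/testthat/edition: 3
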