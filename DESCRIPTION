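Package: sweetgate
Title: Similarity-Gated Expert System for Sweet/Non-Sweet Classification of Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a quantitative structure-taste relationship (QSTR) expert
    system that predicts whether a molecule tastes sweet. Molecules are first
    screened by Jaccard-Tanimoto similarity of their circular (Morgan-style)
    fingerprints against reference clusters of known sweeteners; molecules that
    fail the similarity gate are classified by a strict consensus of two
    independently built classifiers on molecular descriptors: a rank-weighted
    N-nearest-neighbours (N3) classifier and partial least squares discriminant
    analysis (PLSDA). Includes dataset curation from SMILES, V-WSP unsupervised
    correlation-based descriptor reduction, genetic-algorithm variable subset
    selection, venetian-blind cross-validation, rejection-aware classification
    metrics, Monte Carlo validation, and a two-branch applicability-domain
    assessment (leverage and similarity distribution).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    cluster,
    jsonlite,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
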