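Package: mutstab
Title: Sequence-Based Prediction of Mutation-Induced Protein Stability
    Changes with Homology-Aware Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classification and regression of mutation-induced changes in
    protein unfolding free energy (ddGu) from sequence-derived features:
    SIFT scores, PSSM-based mutation and conservation likelihoods,
    predicted secondary structure, accessible surface area, disorder
    probability, and differences in physicochemical amino-acid
    parameters. Implements ProTherm-style dataset curation (condition
    merging, pH-nearest selection, within-cluster deduplication),
    single-linkage homology clustering at a sequence-identity threshold,
    the unseen-mutation / unseen-residue / unseen-protein evaluation
    schemes that expose over-fitting in stability predictors, RBF-kernel
    support vector machines with grid search optimised for Matthews
    correlation coefficient or root mean square error, and a synthetic
    data generator reproducing the per-protein sign correlation and class
    imbalance of experimental stability data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
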