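Package: connbasis
Title: Low-Rank Basis Sets for Inter-Individual Variation in Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and exploiting low-rank structure in
    inter-individual variation of resting-state functional connectomes.
    Converts ROI time series to Fisher-z connectomes, estimates intrinsic
    dimensionality of the subjects-by-edges matrix by the Levina-Bickel
    nearest-neighbour maximum-likelihood method, learns a principal-component
    basis of inter-individual variation with out-of-sample reconstruction
    curves, predicts phenotypes from component expression scores (Brain Basis
    Set modelling) with a connectome-predictive-modelling comparator, tests
    intrinsic-connectivity-network community structure in components with a
    Gaussian weighted stochastic block model permutation test, and quantifies
    test-retest reliability of edges and component scores with ICC(2,1)
    against a permuted-component null.  A synthetic-data generator plants
    block-structured low-rank inter-individual variation so the full pipeline
    can be exercised and validated without access-controlled imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
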