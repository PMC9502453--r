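Package: ms2fp
Title: Molecular Fingerprint Prediction from LC-MS/MS Spectra with Multi-Task Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for predicting 166-bit MACCS substructure fingerprints from
    LC-MS/MS product-ion spectra and using the predicted fingerprints to rank
    candidate structures by Jaccard-Tanimoto similarity. Provides readers for
    MSP-style spectral libraries, a metadata- and spectrum-level curation
    cascade, fixed-grid spectral binning, sparse principal component analysis
    for dimensionality reduction, compound-grouped data splitting, multi-task
    feed-forward networks with per-bit Bayes-optimal thresholds and
    majority-vote ensembling, tree-structured Parzen estimator hyperparameter
    search, multi-task evaluation metrics (non-error rate, Jaccard-Tanimoto
    similarity), chemical-space diagnostics, and a synthetic spectrum-
    fingerprint generator for end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    ChemmineOB,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'mona_io.R'
    'curation.R'
    'vectorize.R'
    'fingerprint.R'
    'dimred.R'
    'split.R'
    'network.R'
    'model.R'
    'tune.R'
    'evaluate.R'
    'synth.R'
    'pipeline.R'
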