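Package: erconsensus
Title: Consensus Modeling of Estrogen Receptor Activity Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for combining heterogeneous in silico predictions of
    estrogen receptor binding, agonist and antagonist activity into
    score-weighted consensus calls. Implements a nine-step chemical
    structure curation workflow producing QSAR-ready structures keyed by
    InChI; harmonization of multi-source literature activity records into
    categorical and five-level potency reference sets; per-model evaluation
    on stratified chemical subsets with balanced-accuracy summary scores;
    weighted categorical and potency consensus with post-hoc consistency
    corrections; and a seeded synthetic-data generator emulating the
    statistical structure of high-throughput screening scores, participant
    model ensembles and noisy literature corpora, so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
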