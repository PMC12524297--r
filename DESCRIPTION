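Package: hazchemnet
Title: Hazardous-Chemical Classification from Molecular Structure with an
    Attention Autoencoder and Mixture-of-Experts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts whether a chemical compound is hazardous from its SMILES
    structure. Molecules are encoded as 512-bit circular (Morgan-style)
    fingerprints concatenated with four physicochemical descriptors (molecular
    weight, logP, hydrogen-bond donor and acceptor counts) into a
    516-dimensional feature vector, standardized, compressed by an
    attention-based autoencoder, and classified by a mixture-of-experts
    network. Includes dataset splitting (7:2:1), stratified repeated k-fold
    cross-validation with mean and standard-deviation reporting, a feature
    ablation harness, an external-validation runner, synthetic-data
    generators for end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
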