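Package: spikemm
Title: Sparse Bayesian Microbe-Metabolite Co-Occurrence Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits a variational Bayesian neural-embedding model that predicts
    metabolite abundance profiles from paired microbial count data. Taxon and
    metabolite features are embedded in a shared low-dimensional latent space;
    metabolite abundances conditional on an observed taxon follow a multinomial
    softmax decoder. A spike-and-slab prior on the taxon embeddings, relaxed
    with a Gumbel-softmax reparameterization, probabilistically selects a
    sparse core set of taxa, with per-taxon inclusion probabilities reported
    alongside co-occurrence log-probabilities. Includes a maximum a posteriori
    baseline, a synthetic paired-omics generator with known ground truth,
    hold-out evaluation metrics (MAE, SMAPE), selection and clustering
    utilities, CSV/TSV/BIOM readers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    vegan,
    pROC,
    withr
Config/testthat/edition: 3
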