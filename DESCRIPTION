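Package: okfire
Title: Bayesian Inference of Replication Origin Firing from Okazaki-Fragment Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers DNA replication origin firing-time distributions, origin
    licencing probabilities and origin-interference (obscuring) rates from
    strand-specific Okazaki-fragment sequencing pile-up profiles over triplets
    of neighbouring origins. Provides a stochastic generative simulator of
    single-cell replication with passive fork collision, an approximate
    log-normal observation model for boxed strand-specific counts, preprocessing
    of bedGraph coverage tracks (strand-bias correction, boxing, local
    normalization), a reversible-jump Markov chain Monte Carlo sampler over
    per-cell latent licencing states and firing times with multi-chain
    Gelman-Rubin diagnostics, and posterior summaries including collision-point
    densities, firing-order probabilities and median replication-time
    reconstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'constructors.R'
    'simulate.R'
    'noise.R'
    'inference.R'
    'okfire-package.R'
    'preprocess.R'
    'summaries.R'
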