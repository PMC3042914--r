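Package: AlignTails
Title: Rare-Event Sampling of Local Alignment Score Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the full null distribution of local alignment scores,
    including the extreme rare-event tail (probabilities below 1e-60), for
    protein sequence comparison with position-dependent scoring. Supports
    three null models: two random i.i.d. sequences, a fixed query against
    random subjects, and queries drawn from a transmembrane-topology hidden
    Markov model. The sampler combines Metropolis-Hastings moves in sequence
    space with Wang-Landau flat-histogram weight estimation and importance
    reweighting; estimated distributions are summarised by a modified Gumbel
    (extreme-value) law with a Gaussian tail correction, from which p-values
    and E-values are derived.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    Biostrings,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
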