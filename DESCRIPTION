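Package: gibbsdbn
Title: Dynamic Bayesian Networks with Gibbs Sampling, Stochastic EM and
    Directional Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Specify dynamic Bayesian networks over sequences as a slice of
    nodes with intra- and inter-slice edges, perform inference over hidden
    discrete nodes by Gibbs sampling, and learn parameters by stochastic EM
    (S-EM) or Monte Carlo EM (MC-EM).  Besides categorical, multinomial,
    Poisson and Gaussian nodes, the package provides first-class support for
    directional statistics: the univariate von Mises distribution on the
    circle, the bivariate von Mises (cosine variant) distribution on the
    torus and the Kent (5-parameter Fisher-Bingham, FB5) distribution on the
    sphere, the families used in probabilistic models of biomolecular
    structure.  Includes an exact forward-algorithm likelihood for HMM-shaped
    models, suspend/resume serialization of training state, a sequence and
    model text-file format, benchmark fixture generators and a command-line
    interface.
License: GPL (>= 2)
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
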