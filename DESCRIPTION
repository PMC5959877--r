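Package: serialwm
Title: Serial Dependence in Visuospatial Working Memory from Short-Term Facilitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models of trial-history interference (serial bias) in visuospatial
    working memory. Implements a sequential Bayesian predictive-distribution
    updater over target angles under an assumed environmental change rate, a
    stochastic ring neural-field simulator of bump attractor dynamics with
    short-term synaptic facilitation, the particle-on-a-potential abstraction
    linking predictive distributions to attractor landscapes via stationary
    Fokker-Planck densities, and a low-dimensional stochastic reduction of the
    bump and facilitation dynamics. Includes generators for delayed-response
    task protocols (uniform and serially correlated target sequences) and
    analyses of bias curves, response spread, and delay-period diffusion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
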