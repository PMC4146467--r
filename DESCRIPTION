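Package: saspnet
Title: Discrete Logical-Network Dynamics of the Speract-Activated
    Calcium Signaling Pathway in Sea Urchin Sperm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-valued logical (generalized Boolean) network modelling of
    the speract-activated Ca2+ signaling pathway (SASP) that shapes sea
    urchin sperm motility. Provides a plain-text truth-table dialect for
    defining networks with mixed binary/ternary nodes, a vectorized
    synchronous update engine with attractor detection, basin-of-attraction
    and transient statistics, in-silico channel knockout/activation
    (clamping) semantics, ensemble-averaged calcium traces over large sets
    of initial conditions, periodogram-based spectral analysis with
    running-average envelope detection, and an effect-matrix report across
    a suite of niflumic-acid-like perturbation scenarios. Ships a
    physiologically motivated synthetic reconstruction of the 21-node SASP
    network plus generators for random and constructed logical networks
    with known attractor structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
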