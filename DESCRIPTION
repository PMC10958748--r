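Package: gapddm
Title: Generalized Drift-Diffusion Modeling of Driver Gap Acceptance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling left-turn gap acceptance decisions as a
    generalized drift-diffusion process. The decision variable accumulates
    noisy evidence at a rate driven by the time-varying time-to-arrival and
    distance of an oncoming vehicle, and terminates at decision boundaries
    that collapse as time-to-arrival shrinks. Includes a Crank-Nicolson
    first-passage-time solver with a matched Monte-Carlo simulator,
    quantile-based weighted least-squares fitting by differential evolution,
    vincentized group-level response-time distributions, hold-one-condition-out
    cross-validation, comparison against simpler evidence-accumulation model
    variants, and a synthetic trial generator emulating a balanced 3x3
    time-to-arrival by distance design.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
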