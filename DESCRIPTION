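Package: moranenv
Title: Fixation and Stationary Dynamics of Birth-Death Processes in
    Randomly Switching Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact fixation probabilities and mean unconditional and
    conditional fixation times for finite-population one-step birth-death
    processes whose transition probabilities depend on an environment that
    itself follows an independent Markov chain (discrete or continuous
    time, any number of environmental states). Includes the
    frequency-dependent Moran process for 2x2 evolutionary games with
    environment-dependent payoffs, a fast-switching effective-rate
    approximation with single-environment closed forms, mutation-selection
    stationary distributions with slow- and fast-switching approximations
    and a distance diagnostic, and a seeded stochastic simulator for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
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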