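Package: ginarchart
Title: Geometric Control Charts for GINAR(1) Count Processes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Exact tools for the first-order integer-valued autoregressive
    process with geometric marginal distribution (GINAR(1), built on binomial
    thinning) and for the upper one-sided geometric control chart used to
    monitor it. Provides the exact transition probabilities and truncated
    transition matrix of the chain, simulation, moment estimation, and a
    Markov-chain (phase-type) run-length engine: run-length pmf, survival and
    hazard functions, ARL, SDRL, percentiles, the overall run length under a
    random geometric initial state, and the Perron-root limiting hazard.
    Numerical verifiers with violation witnesses are included for the
    structural properties of the chain: total positivity of order 2 of the
    transition matrix, PF2 (log-concavity) of run-length distributions,
    likelihood-ratio and usual stochastic orders of discrete laws, and the
    Kalmykov order between transition matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'ginar-model.R'
    'transition-matrix.R'
    'ordering.R'
    'runlength.R'
    'chart-design.R'
    'cli.R'
    'count-series.R'
    'ginarchart-package.R'
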