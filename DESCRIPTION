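Package: asldesign
Title: Optimal Experimental Design for Multi-Delay Arterial Spin Labeling
Version: 0.1.0
Authors@R: person("Morgan", "Carling", email = "mcarling@example.org",
    role = c("aut", "cre"))
Description: Designs pseudo-continuous arterial spin labeling (PCASL)
    perfusion MRI experiments by minimizing Cramer-Rao lower bounds on
    cerebral blood flow (CBF) and arterial transit time (ATT) estimates
    within a fixed scan time. Implements the PCASL general kinetic model
    and its analytic sensitivity functions, Fisher information with D- and
    L-optimality criteria, prior-averaged (pseudo-Bayesian) design over a
    tapered-uniform transit-time prior, a coordinate-exchange search over
    post-labeling delays with multi-slice timing and per-slice prior
    truncation, and validation tools: a Monte Carlo simulator of noisy
    label-control difference data and bounded nonlinear least-squares
    parameter recovery with error metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
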