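Package: abclook
Title: Look-Ahead Parallel Scheduling for ABC Sequential Monte Carlo
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Likelihood-free parameter inference via approximate Bayesian
    computation with a sequential Monte Carlo sampler (ABC-SMC), executed
    under three parallelization strategies on a deterministic simulated
    worker pool: static scheduling (one task per required particle),
    dynamic scheduling (continuous sampling with run-time-bias correction
    by earliest-start selection), and look-ahead scheduling, which fills
    end-of-generation idle time by preemptively sampling the next
    generation from a preliminary proposal. Implements the multi-proposal
    importance-weighting scheme with per-subpopulation normalization and
    effective-sample-size-optimal mixing, Gaussian kernel-mixture
    proposals, fixed and quantile-adaptive acceptance-threshold schedules,
    built-in synthetic test problems with an exact quadrature oracle, and
    exact simulated wall-time and idle-time accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
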