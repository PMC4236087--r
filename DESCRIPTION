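Package: trendrank
Title: Rank-Based Tests for Monotone Ordered Alternatives
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Nonparametric tests for the k-sample ordered alternative
    problem, in which location parameters are hypothesized to be
    nondecreasing across groups. Implements a rank-difference trend
    statistic that accumulates the positive part of combined-sample rank
    differences over all cross-group pairs, together with its exact null
    mean and variance and asymptotic normal inference, alongside the
    Jonckheere-Terpstra, modified Jonckheere-Terpstra, Terpstra-Magel
    k-tuplet, and Cuzick tests. Provides permutation and
    exact-enumeration inference, a simulated-null cutpoint calibration
    protocol with common random numbers, and a Monte Carlo engine for
    size and power studies under normal, shifted-t, exponential, and
    mixed sampling families, plus a command-line interface for testing
    long-format data files and running simulation configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
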