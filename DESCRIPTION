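Package: palinurid
Title: Catch, Effort and Hurdle-Model CPUE Analysis for a Small-Scale
    Spiny Lobster Fishery
Version: 0.1.0
Authors@R:
    person("Sainte Luce", "Fisheries Analytics", email = "dev@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing participatory monitoring data from a
    small-scale, pot-based spiny lobster fishery managed with a periodic
    no-take zone (NTZ). Implements the sample-based raising estimator of
    monthly landings (effort = days x boat activity coefficient x fleet
    size; landings = effort x CPUE), zero-altered (hurdle) Poisson and
    negative-binomial count models of catch per boat-day fitted by direct
    maximum likelihood with likelihood-ratio model simplification,
    catch-composition and compliance statistics (species and berried-female
    proportions, size structure, Kolmogorov-Smirnov comparisons,
    length-length regressions, median earnings), and a seeded synthetic
    fishery generator with known ground truth for validating every
    estimator. CSV input/output and a command-line pipeline tie the steps
    together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
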