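Package: gsminimax
Title: Optimal Multistage Group-Sequential Trial Designs for Continuous Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation of two-arm group-sequential randomised trials
    with normally distributed outcomes and stopping for futility or efficacy at
    each interim analysis. Computes exact operating characteristics (attained
    type I error, power, stagewise stopping probabilities, expected sample size
    and its maximum over the treatment effect) by two independent numerical
    methods: direct multivariate-normal integration and a Markov recursion over
    the sequence of z-statistics. Finds null-optimal, CRD-optimal and
    delta-minimax designs by simulated annealing with a penalty-augmented
    objective, constructs the nonsymmetric triangular design with the
    discrete-monitoring boundary adjustment, builds the admissible-design
    frontier balancing maximum expected against maximum sample size, and
    assesses robustness of the type I error to variance misspecification by
    Monte-Carlo simulation of z- and t-test analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    mvtnorm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
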