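# Worked-scenario specifications and the published five-stage benchmark
# designs (group size and boundaries as printed, 2 d.p.) used to validate
# the operating-characteristics engine.

main_spec <- function(K) {
  design_spec(K, delta1 = 1, sigma = 3, alpha = 0.05, beta = 0.1)
}

case_study_spec <- function(K = 2) {
  design_spec(K, delta1 = 1, sigma = 2.3, alpha = 0.025, beta = 0.2)
}

ref_designs_k5 <- function() {
  list(
    null_optimal = gs_design(40, f = c(-0.24, 0.37, 0.76, 1.09, 1.56),
                             e = c(3.01, 2.47, 2.23, 2.03, 1.56)),
    crd_optimal = gs_design(42, f = c(-0.51, 0.29, 0.83, 1.33, 2.05),
                            e = c(2.14, 2.05, 2.09, 2.15, 2.05)),
    minimax = gs_design(41, f = c(-0.52, 0.34, 0.92, 1.38, 1.83),
                        e = c(2.54, 2.09, 2.03, 1.96, 1.83)),
    triangular = gs_design(42, f = c(-0.85, 0.30, 0.98, 1.49, 1.90),
                           e = c(2.55, 2.10, 1.96, 1.91, 1.90)))
}

# Converged three-stage delta-minimax design for the main scenario at the
# published maximum sample size (189 per arm, group size 63): boundary-only
# annealing optimum, e_max 125.92, attained alpha 0.0500, power 0.9000.
k3_minimax_design <- function() {
  gs_design(63, f = c(0.090338, 1.018843, 1.785534),
            e = c(2.182690, 1.925763, 1.785534))
}

# Monte-Carlo rejection probability of a design by direct simulation of the
# score-statistic increments; independent oracle for the numerical engines.
simulate_rejection <- function(d, spec, delta, reps) {
  theta <- delta - spec$delta0
  dI <- d$n1 / (2 * spec$sigma^2)
  s <- numeric(reps)
  active <- rep(TRUE, reps)
  reject <- logical(reps)
  for (i in seq_len(d$K)) {
    s <- s + rnorm(reps, theta * dI, sqrt(dI))
    z <- s / sqrt(i * dI)
    if (i == d$K) {
      reject[active] <- z[active] > d$e[i]
      active[active] <- FALSE
    } else {
      up <- active & z > d$e[i]
      down <- active & z <= d$f[i]
      reject[up] <- TRUE
      active <- active & !up & !down
    }
  }
  mean(reject)
}
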