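# Three-stage design with binding constraints for the simulation tests.
sim_design <- function() k3_minimax_design()

test_that("modified boundaries are t-quantiles at the normal tail probability", {
  d <- gs_design(41, f = c(0, 1.96), e = c(2.5, 1.96))
  m <- modified_boundaries(d)
  # at analysis 2: 2 * 82 - 2 = 162 df; tail probability is preserved exactly
  expect_equal(pt(m$e[2], df = 162, lower.tail = FALSE),
               pnorm(1.96, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(m$e[2], qt(pnorm(1.96), df = 162), tolerance = 1e-12)
  # a df = 80 threshold at b = 1.96 is about 1.990
  expect_equal(qt(pnorm(1.96), df = 80), 1.990, tolerance = 1e-3)
  # zero maps to zero (median to median); large samples converge to z
  expect_identical(qt(pnorm(0), df = 40), 0)
  big <- modified_boundaries(gs_design(1e5, f = c(0.5, 1.8), e = c(2.2, 1.8)))
  expect_equal(big$e, c(2.2, 1.8), tolerance = 1e-4)
  # t-boundaries are wider than z-boundaries in the tails
  expect_true(all(m$e >= d$e))
  expect_true(m$f[1] <= d$f[1])
  expect_error(modified_boundaries(gs_design(0.5, c(0, 1.8), c(2.2, 1.8))))
})

test_that("single trial paths respect the stopping logic", {
  spec <- main_spec(3)
  d <- sim_design()
  set.seed(1)
  # overwhelming effect: stops at stage 1 for efficacy
  path <- simulate_trial(d, spec, delta_true = 30, sigma_true = 3,
                         method = "z")
  expect_identical(path$stage, 1L)
  expect_identical(path$direction, "efficacy")
  expect_identical(path$n_realized, 63L)
  # no interim stopping: always reaches the final analysis
  d_open <- gs_design(20, f = c(-Inf, -Inf, 1.8), e = c(Inf, Inf, 1.8))
  for (i in 1:5) {
    p <- simulate_trial(d_open, spec, 0.4, 3, "t")
    expect_identical(p$stage, 3L)
    expect_identical(p$n_realized, 60L)
  }
  expect_length(path$statistics, path$stage)
})

test_that("the vectorised simulator agrees with the numerical engine under the design sigma", {
  spec <- main_spec(3)
  d <- sim_design()
  for (delta in c(0, 1)) {
    res <- estimate_error_rates(d, spec, delta_true = delta, sigma_true = 3,
                                method = "z", replicates = 2e5, seed = 42)
    num <- rejection_probability(d, spec, delta)
    expect_lt(abs(res$type_i_or_power - num), 3 * res$mc_se)
    en <- expected_sample_size(d, spec, delta)
    expect_lt(abs(res$mean_sample_size - en), 0.5)
  }
})

test_that("simulation results are bit-reproducible and carry binomial errors", {
  spec <- main_spec(3)
  d <- sim_design()
  a <- estimate_error_rates(d, spec, 0, 4, "t", replicates = 5e4, seed = 7)
  b <- estimate_error_rates(d, spec, 0, 4, "t", replicates = 5e4, seed = 7)
  expect_identical(a$type_i_or_power, b$type_i_or_power)
  expect_identical(a$mean_sample_size, b$mean_sample_size)
  expect_equal(a$mc_se,
               sqrt(a$type_i_or_power * (1 - a$type_i_or_power) / 5e4),
               tolerance = 1e-12)
  expect_identical(a$rejections, as.integer(a$type_i_or_power * 5e4))
})

test_that("z-test type I error inflates with the true sigma; t-corrections hold it", {
  spec <- main_spec(3)
  d <- sim_design()
  reps <- 4e4
  sg <- c(2, 3, 4, 5)
  t1_z <- vapply(seq_along(sg), function(i)
    estimate_error_rates(d, spec, 0, sg[i], "z", reps,
                         seed = 100 + i)$type_i_or_power, numeric(1))
  expect_true(all(diff(t1_z) > 0))
  expect_lt(t1_z[1], 0.01)
  for (i in seq_along(sg)) {
    r <- estimate_error_rates(d, spec, 0, sg[i], "t_modified", reps,
                              seed = 200 + i)
    expect_lt(abs(r$type_i_or_power - spec$alpha), 3 * r$mc_se + 0.002)
  }
})

test_that("the sigma-grid table has one error and one power column per method", {
  spec <- main_spec(3)
  d <- sim_design()
  tab <- error_rate_table(d, spec, sigma_grid = c(3, 4),
                          methods = c("z", "t_modified"),
                          replicates = 5000, seed = 3)
  expect_identical(names(tab),
                   c("sigma_true", "type_i_z", "power_z",
                     "type_i_t_modified", "power_t_modified"))
  expect_identical(nrow(tab), 2L)
  expect_true(all(tab$power_z > tab$type_i_z))
})
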