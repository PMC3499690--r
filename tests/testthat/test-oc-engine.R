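test_that("z-statistic correlation is sqrt(i/j) and matches simulation", {
  expect_equal(z_covariance(3, 3, K = 5), 1)
  expect_equal(z_covariance(1, 2, K = 2), sqrt(1 / 2), tolerance = 1e-12)
  expect_equal(z_covariance(2, 4, K = 4), sqrt(2 / 4), tolerance = 1e-12)
  expect_error(z_covariance(3, 2, K = 5))
  expect_error(z_covariance(0, 2, K = 5))

  # empirical correlation of simulated stagewise z-statistics
  set.seed(42)
  reps <- 2e5
  x1 <- rnorm(reps); x2 <- rnorm(reps)
  z1 <- x1; z2 <- (x1 + x2) / sqrt(2)
  expect_equal(cor(z1, z2), sqrt(1 / 2), tolerance = 0.01)
})

test_that("the z-statistic model has the stated means and covariance", {
  spec <- main_spec(3)
  d <- gs_design(42, f = c(-0.5, 0.3, 1.8), e = c(2.5, 2.1, 1.8))
  m <- z_statistic_model(d, spec, delta = 0.7)
  expect_equal(m$means, 0.7 * sqrt(1:3 * 42 / 18), tolerance = 1e-12)
  expect_true(isSymmetric(m$covariance))
  expect_true(all(eigen(m$covariance, only.values = TRUE)$values > 0))
  expect_equal(m$covariance[1, 3], sqrt(1 / 3), tolerance = 1e-12)
})

test_that("degenerate cases reduce to the one-stage normal test", {
  spec1 <- main_spec(1)
  d1 <- gs_design(155, qnorm(0.95), qnorm(0.95))
  expect_equal(rejection_probability(d1, spec1, 0), 0.05, tolerance = 1e-9)

  spec2 <- main_spec(2)
  d2 <- gs_design(80, f = c(-Inf, 1), e = c(Inf, 1))
  expect_equal(rejection_probability(d2, spec2, 0), 1 - pnorm(1),
               tolerance = 1e-9)
  # no interim stopping: expected sample size is exactly 2 n1
  expect_equal(expected_sample_size(d2, spec2, 0.5), 160, tolerance = 1e-9)
})

test_that("stagewise stopping probabilities obey total probability and symmetry", {
  spec <- main_spec(3)
  for (d in fixture_designs(3, 5, seed = 7)) {
    p <- stage_stopping_probabilities(d, spec, delta = 0.4)
    expect_equal(sum(p$futility) + sum(p$efficacy), 1, tolerance = 1e-8)
    expect_true(all(p$futility >= 0 & p$efficacy >= 0))
  }
  # symmetric boundaries about a zero-mean z-statistic at stage 1
  spec2 <- main_spec(2)
  dsym <- gs_design(60, f = c(-1.3, 1.7), e = c(1.3, 1.7))
  p <- stage_stopping_probabilities(dsym, spec2, delta = 0)
  expect_equal(p$futility[1], p$efficacy[1], tolerance = 1e-9)
})

test_that("direct and Markov engines agree on random designs", {
  direct <- engine_config("direct")
  for (K in 2:5) {
    spec <- main_spec(K)
    for (d in fixture_designs(K, 5, seed = 100 + K)) {
      for (delta in c(0, 0.6, 1)) {
        expect_equal(rejection_probability(d, spec, delta),
                     rejection_probability(d, spec, delta, direct),
                     tolerance = 1e-5)
      }
      expect_equal(expected_sample_size(d, spec, 0.5),
                   expected_sample_size(d, spec, 0.5, direct),
                   tolerance = 1e-5)
    }
  }
})

test_that("rejection probability rises with the effect; stopping splits monotonely", {
  spec <- main_spec(4)
  d <- fixture_designs(4, 1, seed = 3)[[1]]
  grid <- seq(-0.5, 2, by = 0.25)
  rp <- vapply(grid, function(x) rejection_probability(d, spec, x), numeric(1))
  expect_true(all(diff(rp) > 0))
  cum_eff <- vapply(grid, function(x)
    sum(stage_stopping_probabilities(d, spec, x)$efficacy[1:3]), numeric(1))
  cum_fut <- vapply(grid, function(x)
    sum(stage_stopping_probabilities(d, spec, x)$futility[1:3]), numeric(1))
  expect_true(all(diff(cum_eff) > 0))
  expect_true(all(diff(cum_fut) < 0))
})

test_that("the expected-sample-size curve is unimodal in the effect", {
  for (K in c(2, 5)) {
    spec <- main_spec(K)
    for (d in fixture_designs(K, 3, seed = 50 + K)) {
      grid <- seq(spec$delta0 - spec$delta1, spec$delta0 + 3 * spec$delta1,
                  by = 0.05)
      en <- vapply(grid, function(x) expected_sample_size(d, spec, x),
                   numeric(1))
      sign_changes <- sum(diff(sign(diff(en))) != 0)
      expect_lte(sign_changes, 1)
    }
  }
})

test_that("interval search finds the worst-case effect to grid accuracy", {
  spec <- main_spec(3)
  for (d in fixture_designs(3, 3, seed = 9)) {
    wc <- worst_case_delta(d, spec)
    grid <- seq(spec$delta0, spec$delta0 + 2 * spec$delta1, by = 0.001)
    en_grid <- max(vapply(grid, function(x)
      expected_sample_size(d, spec, x), numeric(1)))
    expect_equal(wc$e_max, en_grid, tolerance = 0.02)
    expect_gte(wc$e_max, expected_sample_size(d, spec, spec$delta0) - 1e-6)
    expect_true(d$n1 <= wc$e_max && wc$e_max <= d$K * d$n1)
  }
})

test_that("the worst-case bracket widens (with a warning) when the maximum is outside", {
  spec <- main_spec(2)
  d <- fixture_designs(2, 1, seed = 21)[[1]]
  wc_full <- worst_case_delta(d, spec)
  # start with a bracket that excludes the maximiser
  expect_warning(
    wc <- worst_case_delta(d, spec, bracket = c(spec$delta0,
                                                spec$delta0 + 0.05)),
    "widened")
  expect_equal(wc$e_max, wc_full$e_max, tolerance = 0.05)
})

test_that("Monte-Carlo simulation agrees with the numerical engines", {
  spec <- main_spec(3)
  d <- gs_design(63, f = c(0.0, 0.9, 1.8), e = c(2.5, 2.1, 1.8))
  set.seed(99)
  reps <- 2e5
  for (delta in c(0, 1)) {
    sim <- simulate_rejection(d, spec, delta, reps)
    num <- rejection_probability(d, spec, delta)
    se <- sqrt(num * (1 - num) / reps)
    expect_lt(abs(sim - num), 3 * se)
  }
})

test_that("operating characteristics bundle is internally consistent", {
  spec <- main_spec(5)
  d <- ref_designs_k5()$minimax
  oc <- operating_characteristics(d, spec)
  expect_equal(oc$alpha_attained, rejection_probability(d, spec, 0),
               tolerance = 1e-10)
  expect_equal(oc$power_attained, rejection_probability(d, spec, 1),
               tolerance = 1e-10)
  expect_equal(oc$e_null, expected_sample_size(d, spec, 0), tolerance = 1e-8)
  expect_gte(oc$e_max, max(oc$e_null, oc$e_crd) - 1e-6)
  expect_equal(oc$max_n, 205)
})

test_that("expected-sample-size curves export one column per design", {
  spec <- main_spec(2)
  designs <- list(a = fixture_designs(2, 1, seed = 1)[[1]],
                  b = fixture_designs(2, 1, seed = 2)[[1]])
  cv <- en_curve(designs, spec, deltas = seq(0, 2, by = 0.5))
  expect_identical(names(cv), c("delta", "a", "b"))
  expect_identical(nrow(cv), 5L)
  expect_true(all(cv$a >= designs$a$n1 & cv$a <= 2 * designs$a$n1))
})

test_that("engine configuration enforces its invariants", {
  expect_error(engine_config(grid_points = 16))
  expect_error(engine_config(mvn_tolerance = 1e-4))
  expect_identical(engine_config("direct")$method, "direct")
})
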