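test_that("the feasibility penalty is zero inside and linear outside", {
  spec <- main_spec(2)
  expect_identical(sa_penalty(0.049, 0.10, spec, mu = 155), 0)
  expect_identical(sa_penalty(0.05, 0.1, spec, mu = 155), 0)
  expect_equal(sa_penalty(0.06, 0.12, spec, mu = 155),
               155 * (0.01 / 0.05 + 0.02 / 0.10), tolerance = 1e-10)
  # continuity at the feasibility boundary
  eps <- 1e-9
  expect_lt(sa_penalty(0.05 + eps, 0.1, spec, mu = 155), 1e-4)
  # strictly increasing in each violation
  expect_lt(sa_penalty(0.055, 0.1, spec, 155), sa_penalty(0.06, 0.1, spec, 155))
  expect_lt(sa_penalty(0.05, 0.11, spec, 155), sa_penalty(0.05, 0.12, spec, 155))
})

test_that("the objective equals the base quantity for feasible designs", {
  spec <- main_spec(3)
  d <- k3_minimax_design()
  o <- sa_objective(d, spec, "minimax")
  expect_equal(o[["penalty"]], 0)
  expect_equal(o[["objective"]], o[["base"]], tolerance = 1e-10)
  expect_equal(o[["base"]], worst_case_delta(d, spec)$e_max, tolerance = 1e-6)
  o0 <- sa_objective(d, spec, "null")
  expect_equal(o0[["base"]], expected_sample_size(d, spec, 0), tolerance = 1e-8)
  # the published five-stage boundaries (2 d.p.) sit a hair below the power
  # constraint, so the penalty is small but nonzero
  o5 <- sa_objective(ref_designs_k5()$minimax, main_spec(5), "minimax")
  expect_lt(o5[["penalty"]], 0.5)
})

test_that("candidate proposals have the requested spread and respect constraints", {
  set.seed(5)
  d <- gs_design(77.5, f = c(0, 0.8, 1.64), e = c(2.5, 2.1, 1.64))
  # degenerate proposal variance keeps the design in place
  cand <- propose_candidate(d, 1e-9, 1e-9)
  expect_equal(cand$n1, d$n1, tolerance = 1e-6)
  expect_equal(cand$e, d$e, tolerance = 1e-6)

  draws <- replicate(10000, propose_candidate(d, 5, 0.1)$n1)
  expect_equal(sd(draws), 5, tolerance = 0.03)
  expect_true(all(draws > 0))

  wild <- replicate(500, {
    cd <- propose_candidate(d, 10, 3)
    cd$n1 > 0 && all(cd$e[-3] > cd$f[-3]) && cd$e[3] == cd$f[3]
  })
  expect_true(all(wild))

  set.seed(31)
  a <- propose_candidate(d, 5, 1)
  set.seed(31)
  b <- propose_candidate(d, 5, 1)
  expect_identical(a, b)

  fixed <- propose_candidate(d, 5, 1, fix_n1 = TRUE)
  expect_identical(fixed$n1, d$n1)
})

test_that("the acceptance rule is Metropolis with temperature t_a", {
  expect_true(sa_accept(10, 9.99, t_a = 1))
  expect_true(sa_accept(10, 10, t_a = 1))
  set.seed(8)
  # worse by exactly t_a: long-run acceptance rate e^{-1}
  acc <- replicate(1e5, sa_accept(100, 100 + 2.5, t_a = 2.5))
  expect_equal(mean(acc), exp(-1), tolerance = 0.005)
  # frozen temperature never accepts a worse candidate
  acc0 <- replicate(200, sa_accept(100, 100.01, t_a = 1e-12))
  expect_false(any(acc0))
})

test_that("a one-stage fixed-delta search collapses to the single-stage design", {
  spec <- main_spec(1)
  set.seed(2)
  fit <- run_sa(spec, "crd",
                sa = sa_config(block_iterations = 2000, max_blocks = 6))
  expect_identical(fit$design$n1, 155)
  expect_lte(fit$alpha, spec$alpha + 1e-4)
  expect_gte(fit$power, 1 - spec$beta - 1e-4)
})

test_that("annealing is reproducible and its incumbent never worsens", {
  spec <- main_spec(2)
  cfg <- sa_config(block_iterations = 1500, max_blocks = 4)
  set.seed(77)
  fit1 <- run_sa(spec, "minimax", sa = cfg)
  set.seed(77)
  fit2 <- run_sa(spec, "minimax", sa = cfg)
  expect_identical(fit1$design, fit2$design)
  expect_identical(fit1$objective, fit2$objective)

  # the incumbent never worsens within a phase group (the integer-rounding
  # step between groups legitimately restarts the incumbent)
  for (grp in split(fit1$trace, fit1$trace$phase == "integer")) {
    best_seq <- pmin(grp$best_objective, grp$feasible_objective)
    expect_true(all(diff(best_seq) <= 1e-9))
  }

  # restarting from the returned design cannot worsen the objective
  set.seed(78)
  fit3 <- run_sa(spec, "minimax", sa = cfg, initial = fit1$design)
  expect_lte(fit3$objective, fit1$objective + 1e-6)

  # the returned design is feasible
  expect_lte(fit1$alpha, spec$alpha + 1e-4)
  expect_gte(fit1$power, 1 - spec$beta - 1e-4)
})

test_that("boundary-only searches keep the group size fixed", {
  spec <- main_spec(2)
  init <- gs_design(90, f = c(0.5, 1.75), e = c(2.1, 1.75))
  set.seed(9)
  fit <- run_sa(spec, "minimax",
                sa = sa_config(block_iterations = 1500, max_blocks = 4),
                initial = init, fix_n1 = TRUE)
  expect_identical(fit$design$n1, 90)
  expect_lte(fit$alpha, spec$alpha + 1e-4)
})

test_that("configuration validation catches pathological settings", {
  expect_error(sa_config(rho = 1))
  expect_error(sa_config(rho = 0))
  expect_error(sa_config(t_c2 = -1))
  expect_error(sa_config(mu = 0))
  expect_error(sa_config(block_iterations = 0))
  # a fixed non-positive group size can never produce a valid candidate
  bad <- gs_design(-5, c(0, 1.6), c(2.5, 1.6))
  expect_error(propose_candidate(bad, 1, 1, fix_n1 = TRUE, max_tries = 50L),
               "proposal")
})
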