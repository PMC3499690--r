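test_that("fixture designs are deterministic, valid and engine-consistent", {
  a <- fixture_designs(4, 10, seed = 123)
  b <- fixture_designs(4, 10, seed = 123)
  expect_identical(a, b)
  expect_length(a, 10L)
  for (d in a) expect_true(validate_design(d, 4)$valid)

  direct <- engine_config("direct")
  spec <- main_spec(5)
  for (d in fixture_designs(5, 3, seed = 11)) {
    expect_equal(rejection_probability(d, spec, 0.5),
                 rejection_probability(d, spec, 0.5, direct),
                 tolerance = 1e-5)
  }
})

test_that("scenario specs carry the documented parameters", {
  m <- scenario_spec("main", 5)
  expect_identical(c(m$delta1, m$sigma, m$alpha, m$beta), c(1, 3, 0.05, 0.1))
  cs <- scenario_spec("case_study", 2)
  expect_identical(c(cs$delta1, cs$sigma, cs$alpha, cs$beta),
                   c(1, 2.3, 0.025, 0.2))
})

test_that("an invalid table id is rejected", {
  expect_error(reproduce_table(9), "table_id")
  expect_error(reproduce_table(0), "table_id")
})

test_that("design-summary tables recompute OC values next to the references", {
  ds <- ref_designs_k5()
  tab1 <- reproduce_table(1, designs = list("5" = ds), K = 5)
  expect_identical(nrow(tab1), 4L)
  expect_true(all(c("e_null", "e_null_ref", "e_null_dev",
                    "e_max", "e_max_ref", "e_max_dev") %in% names(tab1)))
  # recomputed values sit on top of the printed ones (2 d.p. boundaries)
  expect_lt(max(tab1$e_null_dev), 0.3)
  expect_lt(max(tab1$e_max_dev), 0.3)
  expect_lt(max(tab1$max_n_dev), 1e-9)

  tab2 <- reproduce_table(2, designs = ds)
  tri <- tab2[tab2$design == "triangular", ]
  expect_equal(tri$n1, 42)
  expect_lt(max(tab2$n1_dev), 1e-9)
})

test_that("the command-line front end round-trips a design through JSON", {
  cli <- file.path(system.file(package = "gsminimax"), "exec", "gsminimax")
  expect_true(file.exists(cli))
  dir <- withr::local_tempdir()
  dpath <- file.path(dir, "design.json")
  opath <- file.path(dir, "oc.json")
  d <- gs_design(63, f = c(0.09, 1.02, 1.79), e = c(2.18, 1.93, 1.79))
  write_design(d, dpath)
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  status <- system2("Rscript",
                    c(cli, "oc", "--design", dpath, "--stages", "3",
                      "--delta1", "1", "--sigma", "3", "--out", opath),
                    env = env, stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  oc <- jsonlite::read_json(opath, simplifyVector = TRUE)
  spec <- main_spec(3)
  expect_equal(oc$alpha_attained, rejection_probability(d, spec, 0),
               tolerance = 1e-8)
  expect_equal(oc$e_max, worst_case_delta(d, spec)$e_max, tolerance = 1e-6)
  # a design read back from JSON is identical to the one written
  expect_identical(read_design(dpath)$f, d$f)

  # validation failures surface as exit code 2
  bad <- system2("Rscript", c(cli, "oc", "--design", dpath, "--stages", "3",
                              "--delta1", "1"),
                 env = env, stdout = FALSE, stderr = FALSE)
  expect_identical(bad, 2L) # --sigma missing
})

test_that("the variance table reproduces its reference layout at small scale", {
  d <- gs_design(63, f = c(-0.24, 0.77, 1.82), e = c(2.37, 2.05, 1.82))
  tab <- reproduce_table(3, designs = d, replicates = 4000, seed = 5)
  expect_identical(nrow(tab), 9L)
  expect_true(all(c("type_i_z", "type_i_z_ref", "power_t_modified_ref")
                  %in% names(tab)))
  # coarse agreement at this replicate count: the sigma = 1 z-test never rejects
  expect_lt(tab$type_i_z[1], 0.005)
})
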