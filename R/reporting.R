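#' Random valid designs for property testing
#'
#' Generates `count` structurally valid designs with monotone boundary
#' shapes: efficacy boundaries decrease towards, and futility boundaries
#' increase towards, a common final value, so `e_k > f_k` holds at every
#' interim analysis by construction.  Deterministic for a given seed.
#'
#' @param K number of stages.
#' @param count number of designs.
#' @param seed integer seed.
#' @return List of [gs_design()] objects.
#' @export
fixture_designs <- function(K, count, seed) {
  stopifnot(K >= 1, count >= 1)
  set.seed(seed)
  out <- vector("list", count)
  for (i in seq_len(count)) {
    n1 <- runif(1, 15, 90)
    bK <- runif(1, 1.2, 2.2)
    if (K == 1L) {
      out[[i]] <- gs_design(n1, bK, bK)
    } else {
      e <- bK + rev(cumsum(c(0, runif(K - 1, 0.05, 0.6))))
      f <- bK - rev(cumsum(c(0, runif(K - 1, 0.1, 0.9))))
      out[[i]] <- gs_design(n1, f, e)
    }
  }
  out
}

# Published benchmark values for the two worked scenarios, used for the
# side-by-side columns of reproduce_table(); NA where no value is in print.
reference_scenarios <- function() {
  list(
    main = list( # delta0 = 0, delta1 = 1, sigma = 3, alpha = 0.05, beta = 0.1
      table1 = data.frame(
        K = rep(c(2, 3, 4, 5), each = 4),
        design = rep(c("null_optimal", "crd_optimal", "minimax", "triangular"), 4),
        e_null = c(107.6, 118.0, 110.9, 111.2, 94.9, 105.7, 98.0, 100.4,
                   88.7, 98.0, 92.7, 98.3, 85.4, 92.1, 89.2, 96.0),
        e_crd = c(130.5, 117.1, 119.4, 117.6, 128.9, 107.0, 109.2, 108.4,
                  119.1, 102.2, 105.0, 106.1, 113.1, 99.3, 102.8, 103.9),
        e_max = c(138.9, 136.8, 133.3, 132.2, 137.3, 130.0, 125.9, 125.5,
                  130.6, 125.5, 122.0, 124.9, 126.8, 122.5, 119.6, 123.0),
        max_n = c(170, 172, 180, 180, 183, 186, 189, 192,
                  192, 196, 196, 204, 200, 210, 205, 210)),
      table2 = data.frame(
        design = c("null_optimal", "crd_optimal", "minimax", "triangular"),
        n1 = c(40, 42, 41, 42),
        f1 = c(-0.24, -0.51, -0.52, -0.85), e1 = c(3.01, 2.14, 2.54, 2.55),
        f2 = c(0.37, 0.29, 0.34, 0.30),    e2 = c(2.47, 2.05, 2.09, 2.10),
        f3 = c(0.76, 0.83, 0.92, 0.98),    e3 = c(2.23, 2.09, 2.03, 1.96),
        f4 = c(1.09, 1.33, 1.38, 1.49),    e4 = c(2.03, 2.15, 1.96, 1.91),
        f5 = c(1.56, 2.05, 1.83, 1.90),    e5 = c(1.56, 2.05, 1.83, 1.90)),
      table3 = data.frame(
        sigma_true = c(1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5),
        type_i_z = c(0, 0, 0, 0.021, 0.050, 0.086, 0.124, 0.158, 0.189),
        type_i_t = c(0.051, 0.052, 0.051, 0.052, 0.051, 0.052, 0.052, 0.052, 0.051),
        type_i_t_modified = c(0.050, 0.050, 0.050, 0.050, 0.050, 0.050, 0.051, 0.051, 0.050),
        power_z = c(1, 0.998, 0.984, 0.95, 0.900, 0.851, 0.807, 0.768, 0.737),
        power_t = c(1, 1, 0.995, 0.965, 0.900, 0.810, 0.714, 0.626, 0.550),
        power_t_modified = c(1, 1, 0.995, 0.965, 0.899, 0.809, 0.712, 0.623, 0.547))),
    case_study = list( # delta1 = 1, sigma = 2.3, alpha = 0.025, beta = 0.2, K = 2
      table4 = data.frame(
        max_n = c(84, 86, 88, 90, 92, 94, 96),
        e_null = c(63.41, 60.03, 56.27, 56.02, 55.63, 55.56, 55.61),
        e_max = c(77.38, 74.96, 73.10, 72.44, 71.98, 71.74, 71.70),
        e_crd = c(74.23, 71.08, 70.40, 69.50, 69.18, 69.05, 69.18),
        ratio_single_stage = c(1, 1.02, 1.05, 1.07, 1.10, 1.12, 1.14),
        p_low = c(0, 0.453, 0.519, 0.752, 0.814, 0.894, 0.978),
        p_high = c(0.453, 0.519, 0.752, 0.814, 0.894, 0.978, 1))))
}

#' Default specifications of the two worked scenarios
#'
#' `"main"` is the multistage comparison scenario (`delta1 = 1`,
#' `sigma = 3`, `alpha = 0.05`, `beta = 0.1`); `"case_study"` the
#' two-stage diabetic-neuropathic-pain trial scenario (`delta1 = 1`,
#' `sigma = 2.3`, `alpha = 0.025`, `beta = 0.2`).
#'
#' @param scenario `"main"` or `"case_study"`.
#' @param K number of stages.
#' @return A [design_spec()].
#' @export
scenario_spec <- function(scenario = c("main", "case_study"), K) {
  switch(match.arg(scenario),
    main = design_spec(K, delta1 = 1, sigma = 3, alpha = 0.05, beta = 0.1),
    case_study = design_spec(K, delta1 = 1, sigma = 2.3, alpha = 0.025,
                             beta = 0.2))
}

#' Recompute a benchmark table
#'
#' Rebuilds one of the four benchmark tables for the worked scenarios and
#' appends the published reference value plus the absolute deviation next to
#' every recomputed quantity.
#'
#' * `1` — expected and maximum sample sizes of the null-optimal,
#'   CRD-optimal, delta-minimax and triangular designs (main scenario).
#'   By default only `K = 2` and `K = 5` are rebuilt.
#' * `2` — parameters of the four five-stage designs (main scenario).
#' * `3` — type I error and power under variance misspecification for the
#'   three-stage delta-minimax design (main scenario).
#' * `4` — the admissible two-stage designs of the case study.
#'
#' Tables 1-3 need optimised designs; supply them via `designs` (a named
#' list, per K for table 1) to skip the annealing runs, otherwise they are
#' recomputed with `sa`.
#'
#' @param table_id 1, 2, 3 or 4.
#' @param designs optional precomputed designs.  Table 1: named list with
#'   one element per `K` (names `"2"`, `"5"`, ...), each a named list of
#'   [gs_design()]s (`null_optimal`, `crd_optimal`, `minimax`,
#'   `triangular`).  Table 2: the `"5"` element of the same structure.
#'   Table 3: a single three-stage `gsd_design` (the delta-minimax design).
#' @param K stage counts to rebuild for table 1.
#' @param sa a [sa_config()] for any annealing runs required.
#' @param engine an [engine_config()].
#' @param replicates Monte-Carlo replicates for table 3.
#' @param seed integer seed for annealing and simulation.
#' @return A `data.frame`; recomputed columns carry `_ref` and `_dev`
#'   companions where a published value exists.
#' @export
reproduce_table <- function(table_id, designs = NULL, K = c(2, 5),
                            sa = sa_config(), engine = engine_config(),
                            replicates = 50000, seed = 1) {
  if (!table_id %in% 1:4)
    stop("`table_id` must be 1, 2, 3 or 4", call. = FALSE)
  refs <- reference_scenarios()
  set.seed(seed)
  if (table_id == 1) {
    rows <- list()
    for (k in K) {
      spec <- scenario_spec("main", k)
      ds <- if (!is.null(designs)) designs[[as.character(k)]] else
        optimise_scenario_designs(spec, sa, engine)
      for (nm in names(ds)) {
        oc <- operating_characteristics(ds[[nm]], spec, engine)
        rows[[length(rows) + 1L]] <- data.frame(
          K = k, design = nm, e_null = oc$e_null, e_crd = oc$e_crd,
          e_max = oc$e_max, max_n = oc$max_n)
      }
    }
    out <- do.call(rbind, rows)
    return(join_reference(out, refs$main$table1, by = c("K", "design"),
                          cols = c("e_null", "e_crd", "e_max", "max_n")))
  }
  if (table_id == 2) {
    spec <- scenario_spec("main", 5)
    ds <- if (!is.null(designs)) designs else
      optimise_scenario_designs(spec, sa, engine)
    out <- do.call(rbind, lapply(names(ds), function(nm)
      cbind(design = nm, design_to_row(ds[[nm]]))))
    return(join_reference(out, refs$main$table2, by = "design",
                          cols = setdiff(names(refs$main$table2), "design")))
  }
  if (table_id == 3) {
    spec <- scenario_spec("main", 3)
    d <- if (!is.null(designs)) designs else
      run_sa(spec, "minimax", sa = sa, engine = engine)$design
    ref <- refs$main$table3
    out <- error_rate_table(d, spec, ref$sigma_true, replicates = replicates,
                            seed = seed)
    names(out) <- sub("t_modified$", "t_modified", names(out))
    return(join_reference(out, ref, by = "sigma_true",
                          cols = setdiff(names(ref), "sigma_true")))
  }
  # table 4
  spec <- scenario_spec("case_study", 2)
  fr <- admissible_set(design_frontier(spec, sa = sa, engine = engine))
  out <- as.data.frame(fr)[, c("max_n", "e_null", "e_max", "e_crd",
                               "ratio_single_stage", "p_low", "p_high")]
  join_reference(out, refs$case_study$table4, by = "max_n",
                 cols = setdiff(names(refs$case_study$table4), "max_n"))
}

optimise_scenario_designs <- function(spec, sa, engine) {
  list(null_optimal = run_sa(spec, "null", sa = sa, engine = engine)$design,
       crd_optimal = run_sa(spec, "crd", sa = sa, engine = engine)$design,
       minimax = run_sa(spec, "minimax", sa = sa, engine = engine)$design,
       triangular = triangular_design(spec))
}

# Append `<col>_ref` and `<col>_dev` columns by matching on `by`; internal.
join_reference <- function(out, ref, by, cols) {
  key_out <- do.call(paste, c(out[by], sep = "\r"))
  key_ref <- do.call(paste, c(ref[by], sep = "\r"))
  idx <- match(key_out, key_ref)
  for (cl in cols) {
    if (!cl %in% names(out)) next
    out[[paste0(cl, "_ref")]] <- ref[[cl]][idx]
    out[[paste0(cl, "_dev")]] <- abs(out[[cl]] - ref[[cl]][idx])
  }
  out
}
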