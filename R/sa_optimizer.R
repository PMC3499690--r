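#' Simulated-annealing configuration
#'
#' Three temperatures drive the search: `t_c1` is the proposal *variance*
#' for the group size, `t_c2` the proposal variance for each boundary
#' coordinate, and `t_a` the acceptance temperature of the Metropolis rule.
#' All three are multiplied by `rho` after every iteration and reset at the
#' start of each block.  Full-temperature blocks repeat until one fails to
#' improve the best objective by `improvement_tolerance`; they are followed
#' by refinement blocks whose starting temperatures are divided by
#' `refine_factor`, which polish the final fraction of a patient that the
#' full-temperature restarts cannot resolve (a refinement phase stops after
#' two consecutive blocks without improvement).  Every block restarts the
#' chain from the best design found so far.  Defaults follow the tuning
#' that works well for this problem class: `t_c1` = 10% of the single-stage
#' sample size (resolved at run time when left `NULL`), `t_c2 = 3`,
#' `t_a = 100`, `rho = 0.999`, blocks of 10000 iterations.  `mu` is the
#' scale of the feasibility penalty; it defaults to the single-stage sample
#' size.
#'
#' @param t_c1 proposal variance for `n1`; `NULL` resolves to `0.1 *
#'   single_stage_n(spec)` when the search starts.
#' @param t_c2 proposal variance for each boundary coordinate.
#' @param t_a acceptance temperature.
#' @param rho per-iteration geometric cooling factor, in (0, 1).
#' @param mu penalty scale; `NULL` resolves to `single_stage_n(spec)`.
#' @param block_iterations iterations per annealing block.
#' @param improvement_tolerance minimum decrease of the best objective
#'   (patients per arm) for a block to count as an improvement.
#' @param max_blocks safety cap on the number of blocks per phase.
#' @param refine_factor temperature divisor for the refinement blocks.
#' @return An object of class `gsd_sa_config`.
#' @export
sa_config <- function(t_c1 = NULL, t_c2 = 3, t_a = 100, rho = 0.999,
                      mu = NULL, block_iterations = 10000L,
                      improvement_tolerance = 0.01, max_blocks = 20L,
                      refine_factor = 100) {
  if (rho <= 0 || rho >= 1) stop("`rho` must lie in (0, 1)", call. = FALSE)
  if (!is.null(t_c1) && t_c1 <= 0) stop("`t_c1` must be positive", call. = FALSE)
  if (t_c2 <= 0 || t_a <= 0) stop("temperatures must be positive", call. = FALSE)
  if (!is.null(mu) && mu <= 0) stop("`mu` must be positive", call. = FALSE)
  if (block_iterations < 1) stop("`block_iterations` must be >= 1", call. = FALSE)
  if (refine_factor < 1) stop("`refine_factor` must be >= 1", call. = FALSE)
  structure(list(t_c1 = t_c1, t_c2 = t_c2, t_a = t_a, rho = rho, mu = mu,
                 block_iterations = as.integer(block_iterations),
                 improvement_tolerance = improvement_tolerance,
                 max_blocks = as.integer(max_blocks),
                 refine_factor = refine_factor),
            class = "gsd_sa_config")
}

#' Feasibility penalty
#'
#' Zero for feasible designs; for violations, each error probability
#' contributes `mu` times its relative excess, so a violation proportional to
#' its target incurs a penalty of order `mu` and near-feasible designs are
#' penalised less than grossly infeasible ones.  The penalty is continuous at
#' the feasibility boundary.
#'
#' @param alpha_attained,beta_attained attained error probabilities.
#' @param spec a [design_spec()].
#' @param mu penalty scale (typically the single-stage sample size).
#' @return A nonnegative number.
#' @examples
#' spec <- design_spec(2, delta1 = 1, sigma = 3, alpha = 0.05, beta = 0.1)
#' sa_penalty(0.06, 0.12, spec, mu = 155) # 155 * (0.01/0.05 + 0.02/0.10)
#' @export
sa_penalty <- function(alpha_attained, beta_attained, spec, mu) {
  stopifnot(inherits(spec, "gsd_spec"))
  mu * (pmax(0, (alpha_attained - spec$alpha) / spec$alpha) +
        pmax(0, (beta_attained - spec$beta) / spec$beta))
}

#' Penalty-augmented design objective
#'
#' For `target = "minimax"` the objective is the maximum expected sample size
#' plus the feasibility penalty; for `"null"` or `"crd"` it is the expected
#' sample size at `delta0` or `delta1` plus the penalty.
#'
#' @param d a [gs_design()].
#' @param spec a [design_spec()].
#' @param target `"minimax"`, `"null"` or `"crd"`.
#' @param engine an [engine_config()].
#' @param mu penalty scale; defaults to [single_stage_n()].
#' @return Named numeric vector with components `objective`, `base`,
#'   `alpha_attained`, `power_attained` and `penalty`.
#' @export
sa_objective <- function(d, spec, target = c("minimax", "null", "crd"),
                         engine = engine_config(), mu = NULL) {
  target <- match.arg(target)
  stop_if_invalid(d)
  if (is.null(mu)) mu <- single_stage_n(spec)
  if (engine$method == "markov") {
    tcode <- c(null = 0L, crd = 1L, minimax = 2L)[[target]]
    return(.cpp_objective(d$n1, d$f, d$e, spec$sigma,
                          spec$delta1 - spec$delta0, spec$alpha, spec$beta,
                          mu, tcode, engine$grid_points,
                          2 * (spec$delta1 - spec$delta0), 1e-4))
  }
  alpha_att <- rejection_probability(d, spec, spec$delta0, engine)
  pow <- rejection_probability(d, spec, spec$delta1, engine)
  pen <- sa_penalty(alpha_att, 1 - pow, spec, mu)
  base <- switch(target,
    minimax = worst_case_delta(d, spec, engine)$e_max,
    null = expected_sample_size(d, spec, spec$delta0, engine),
    crd = expected_sample_size(d, spec, spec$delta1, engine))
  c(objective = base + pen, base = base, alpha_attained = alpha_att,
    power_attained = pow, penalty = pen)
}

#' Propose a candidate design
#'
#' Perturbs the current design with independent Gaussian noise: SD `t_c1` on
#' the group size (untouched when `fix_n1`) and SD `t_c2` on each of the
#' `2K - 1` free boundary coordinates (the final futility boundary is tied to
#' the final efficacy boundary).  Candidates are redrawn until the structural
#' constraints `n1 > 0` and `e_k > f_k` (k < K) hold.
#'
#' @param d current [gs_design()].
#' @param t_c1,t_c2 proposal standard deviations.
#' @param fix_n1 keep the group size fixed (boundary-only search).
#' @param max_tries abort after this many consecutive invalid proposals.
#' @return A valid `gsd_design`.
#' @export
propose_candidate <- function(d, t_c1, t_c2, fix_n1 = FALSE,
                              max_tries = 10000L) {
  K <- d$K
  for (i in seq_len(max_tries)) {
    n1 <- if (fix_n1) d$n1 else d$n1 + rnorm(1L, 0, t_c1)
    if (K > 1L) {
      f <- d$f
      f[-K] <- f[-K] + rnorm(K - 1L, 0, t_c2)
      e <- d$e + rnorm(K, 0, t_c2)
      f[K] <- e[K]
    } else {
      e <- d$e + rnorm(1L, 0, t_c2)
      f <- e
    }
    if (n1 > 0 && (K == 1L || all(e[-K] > f[-K])))
      return(gs_design(n1, f, e))
  }
  stop("no valid candidate design after ", max_tries,
       " proposals; proposal temperatures look pathological", call. = FALSE)
}

#' Metropolis acceptance rule
#'
#' Accept with probability 1 when the candidate does not worsen the
#' objective, and with probability `exp(-(f_candidate - f_current) / t_a)`
#' otherwise.
#'
#' @param f_current,f_candidate objective values.
#' @param t_a acceptance temperature, `> 0`.
#' @return Logical.
#' @export
sa_accept <- function(f_current, f_candidate, t_a) {
  stopifnot(t_a > 0)
  if (f_candidate <= f_current) return(TRUE)
  runif(1L) < exp(-(f_candidate - f_current) / t_a)
}

# Default starting design, chosen by target.  For the minimax and
# CRD-optimal criteria the closed-form triangular design: it is immediate to
# construct and sits next to those optima (the families have near-identical
# expected-sample-size behaviour), so the anneal starts inside the right
# basin — a generic start leaves the chain, for K >= 3, in the basin of the
# no-early-stopping design.  The null-optimal shape (steep early futility
# boundaries) is closer to the interpolated start.  For K = 1 the
# single-stage test.
initial_design <- function(spec, target = "minimax") {
  K <- spec$K
  zf <- qnorm(1 - spec$alpha)
  if (K == 1L) return(gs_design(single_stage_n(spec), zf, zf))
  if (target == "null") return(interpolated_design(spec, single_stage_n(spec) / K))
  triangular_design(spec)
}

# Interpolated-boundary start: futility 0 -> z_{1-alpha}, efficacy
# 2.5 -> z_{1-alpha}.
interpolated_design <- function(spec, n1) {
  K <- spec$K
  zf <- qnorm(1 - spec$alpha)
  if (K == 1L) return(gs_design(n1, zf, zf))
  gs_design(n1, f = seq(0, zf, length.out = K),
            e = seq(2.5, zf, length.out = K))
}

# One annealing block: temperature triple (variances v_c1, v_c2 and
# acceptance t_a) cools by rho each iteration; proposal SDs are the square
# roots of the variances.  The penalized objective drives the Metropolis
# chain and its incumbent `best`; the best design that is feasible at the
# final-check tolerance is tracked separately because the penalized optimum
# can sit marginally inside the infeasible region.
sa_block <- function(state, spec, tcode, sa, engine, mu, fix_n1, temps) {
  v_c1 <- temps[1]; v_c2 <- temps[2]; t_a <- temps[3]
  theta1 <- spec$delta1 - spec$delta0
  cur <- state$current; fcur <- state$current_objective
  best <- state$best; fbest <- state$best_objective
  feas <- state$feasible; ffeas <- state$feasible_objective
  for (i in seq_len(sa$block_iterations)) {
    cand <- propose_candidate(cur, sqrt(v_c1), sqrt(v_c2), fix_n1 = fix_n1)
    obj <- .cpp_objective(cand$n1, cand$f, cand$e, spec$sigma, theta1,
                          spec$alpha, spec$beta, mu, tcode,
                          engine$grid_points, 2 * theta1, 1e-4)
    fcand <- obj[["objective"]]
    if (obj[["penalty"]] == 0 && fcand < ffeas) { feas <- cand; ffeas <- fcand }
    if (sa_accept(fcur, fcand, t_a)) {
      cur <- cand; fcur <- fcand
      if (fcand < fbest) { best <- cand; fbest <- fcand }
    }
    v_c1 <- v_c1 * sa$rho; v_c2 <- v_c2 * sa$rho; t_a <- t_a * sa$rho
  }
  list(current = cur, current_objective = fcur,
       best = best, best_objective = fbest,
       feasible = feas, feasible_objective = ffeas)
}

# Error-rate feasibility at the relaxed final-check tolerance.
feasible_at_tolerance <- function(obj, spec) {
  obj[["alpha_attained"]] <= spec$alpha + 1e-4 &&
    obj[["power_attained"]] >= 1 - spec$beta - 1e-4
}

# Run blocks at the given starting temperatures until `patience` consecutive
# blocks fail to improve the incumbent by the improvement tolerance.  Each
# block restarts the chain from the best design found so far (preferring the
# best feasible one).
run_phase <- function(state, spec, tcode, sa, engine, mu, fix_n1, phase,
                      trace, temps, patience = 1L) {
  stalled <- 0L
  for (b in seq_len(sa$max_blocks)) {
    before <- min(state$best_objective, state$feasible_objective)
    if (!is.null(state$feasible) &&
        state$feasible_objective <= state$best_objective) {
      state$current <- state$feasible
      state$current_objective <- state$feasible_objective
    } else {
      state$current <- state$best
      state$current_objective <- state$best_objective
    }
    state <- sa_block(state, spec, tcode, sa, engine, mu, fix_n1, temps)
    trace[[length(trace) + 1L]] <- data.frame(
      phase = phase, block = b, best_objective = state$best_objective,
      feasible_objective = state$feasible_objective,
      current_objective = state$current_objective, n1 = state$best$n1)
    after <- min(state$best_objective, state$feasible_objective)
    stalled <- if (before - after < sa$improvement_tolerance)
      stalled + 1L else 0L
    if (stalled >= patience) break
  }
  list(state = state, trace = trace)
}

#' Optimise a design by simulated annealing
#'
#' Minimises the penalty-augmented objective in two phases.  Phase one
#' treats the group size as continuous: full-temperature annealing blocks
#' (temperatures reset at each block start, chain restarted from the best
#' design so far) run until one fails to improve the best objective by
#' [sa_config()]'s `improvement_tolerance`, then refinement blocks at
#' temperatures divided by `refine_factor` polish the result.  The group
#' size of the best design is then rounded to the nearest integer and phase
#' two re-anneals the stopping boundaries only (refinement temperatures,
#' since the boundaries start near their optimum).  The returned design
#' must pass a final feasibility check at the engine's precision (attained
#' alpha <= alpha + 1e-4, power >= 1 - beta - 1e-4); otherwise an error
#' reporting the best attained error rates is raised.
#'
#' @param spec a [design_spec()].
#' @param target `"minimax"`, `"null"` or `"crd"`.
#' @param sa a [sa_config()].
#' @param engine an [engine_config()] (the annealing loop requires the
#'   Markov engine; the direct engine may still be used afterwards to verify
#'   the result).
#' @param initial optional starting [gs_design()]; by default the
#'   closed-form triangular design (for `K >= 2`), which starts the chain in
#'   the basin of the optimal stopping shapes.
#' @param fix_n1 keep the group size fixed throughout (used by the
#'   admissible-frontier search); phase one is then skipped.
#' @return An object of class `gsd_sa_fit`: list with the optimised `design`,
#'   its `objective`, attained `alpha`, `power`, `e_max`/`delta_star` (for
#'   any target), and a block-level `trace` data frame.
#' @examples
#' \donttest{
#' spec <- design_spec(2, delta1 = 1, sigma = 3, alpha = 0.05, beta = 0.1)
#' set.seed(1)
#' fit <- run_sa(spec, "minimax")
#' fit$design
#' }
#' @export
run_sa <- function(spec, target = c("minimax", "null", "crd"),
                   sa = sa_config(), engine = engine_config(),
                   initial = NULL, fix_n1 = FALSE) {
  target <- match.arg(target)
  stopifnot(inherits(spec, "gsd_spec"))
  if (engine$method != "markov")
    engine <- engine_config("markov", grid_points = engine$grid_points)
  ss_n <- single_stage_n(spec)
  if (is.null(sa$t_c1)) sa$t_c1 <- 0.1 * ss_n
  if (is.null(sa$mu)) sa$mu <- ss_n
  if (is.null(initial)) initial <- initial_design(spec, target)
  stop_if_invalid(initial, spec$K)
  tcode <- c(null = 0L, crd = 1L, minimax = 2L)[[target]]
  obj0 <- sa_objective(initial, spec, target, engine, sa$mu)
  f0 <- obj0[["objective"]]
  ok0 <- obj0[["penalty"]] == 0
  state <- list(current = initial, current_objective = f0,
                best = initial, best_objective = f0,
                feasible = if (ok0) initial else NULL,
                feasible_objective = if (ok0) f0 else Inf)
  trace <- list()
  hot <- c(sa$t_c1, sa$t_c2, sa$t_a)
  mid <- hot / sqrt(sa$refine_factor)
  cold <- hot / sa$refine_factor

  if (!fix_n1) {
    res <- run_phase(state, spec, tcode, sa, engine, sa$mu, FALSE,
                     "explore", trace, hot, patience = 1L)
    state <- res$state; trace <- res$trace
    res <- run_phase(state, spec, tcode, sa, engine, sa$mu, FALSE,
                     "refine-mid", trace, mid, patience = 2L)
    state <- res$state; trace <- res$trace
    res <- run_phase(state, spec, tcode, sa, engine, sa$mu, FALSE,
                     "refine", trace, cold, patience = 2L)
    state <- res$state; trace <- res$trace
    # phase two: integer group size, boundaries only.  Rounding the group
    # size down can cross the power constraint so that no exactly feasible
    # boundaries exist; in that case retry one group larger.
    carry <- if (!is.null(state$feasible)) state$feasible else state$best
    for (n1_int in max(1, round(carry$n1)) + 0:1) {
      rounded <- gs_design(n1_int, carry$f, carry$e)
      objr <- sa_objective(rounded, spec, target, engine, sa$mu)
      fr <- objr[["objective"]]
      okr <- objr[["penalty"]] == 0
      state <- list(current = rounded, current_objective = fr,
                    best = rounded, best_objective = fr,
                    feasible = if (okr) rounded else NULL,
                    feasible_objective = if (okr) fr else Inf)
      res <- run_phase(state, spec, tcode, sa, engine, sa$mu, TRUE,
                       "integer", trace, cold, patience = 2L)
      state <- res$state; trace <- res$trace
      if (!is.null(state$feasible)) break
    }
  } else {
    res <- run_phase(state, spec, tcode, sa, engine, sa$mu, TRUE,
                     "boundary-explore", trace, hot, patience = 1L)
    state <- res$state; trace <- res$trace
    res <- run_phase(state, spec, tcode, sa, engine, sa$mu, TRUE,
                     "boundary-refine", trace, cold, patience = 2L)
    state <- res$state; trace <- res$trace
  }

  best <- state$feasible
  if (is.null(best)) {
    final <- sa_objective(state$best, spec, target, engine, sa$mu)
    if (!feasible_at_tolerance(final, spec))
      stop(sprintf(
        "no feasible design found: best attained alpha = %.4f, power = %.4f",
        final[["alpha_attained"]], final[["power_attained"]]), call. = FALSE)
    warning("returning a design feasible only within the 1e-4 tolerance",
            call. = FALSE)
    best <- state$best
  }
  final <- sa_objective(best, spec, target, engine, sa$mu)
  if (final[["alpha_attained"]] > spec$alpha + 1e-4 ||
      final[["power_attained"]] < 1 - spec$beta - 1e-4)
    stop(sprintf(
      "no feasible design found: best attained alpha = %.4f, power = %.4f",
      final[["alpha_attained"]], final[["power_attained"]]), call. = FALSE)
  wc <- worst_case_delta(best, spec, engine)
  structure(list(
    design = best,
    objective = final[["objective"]],
    alpha = final[["alpha_attained"]],
    power = final[["power_attained"]],
    delta_star = wc$delta_star,
    e_max = wc$e_max,
    target = target,
    spec = spec,
    trace = do.call(rbind, trace)
  ), class = "gsd_sa_fit")
}

#' @export
print.gsd_sa_fit <- function(x, ...) {
  cat(sprintf("Simulated-annealing fit (target = %s)\n", x$target))
  print(x$design)
  cat(sprintf("  objective = %.2f, attained alpha = %.4f, power = %.4f\n",
              x$objective, x$alpha, x$power))
  cat(sprintf("  E_max = %.2f at delta* = %.3f\n", x$e_max, x$delta_star))
  invisible(x)
}

#' Find an optimal design (convenience wrapper)
#'
#' Runs [run_sa()] for the requested optimality criterion.
#'
#' @inheritParams run_sa
#' @param criterion `"null"`, `"crd"` or `"minimax"`.
#' @return A `gsd_sa_fit`.
#' @export
optimal_design <- function(spec, criterion = c("minimax", "null", "crd"),
                           sa = sa_config(), engine = engine_config(),
                           initial = NULL) {
  run_sa(spec, match.arg(criterion), sa = sa, engine = engine,
         initial = initial)
}
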