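#' Numerical engine configuration
#'
#' Two independent methods compute boundary-crossing probabilities.
#' `"markov"` exploits the Markov property of the z-statistic sequence and
#' propagates the continuation sub-density stage by stage with Gauss-Legendre
#' quadrature (`grid_points` nodes per stage, support truncated at 8
#' conditional standard deviations).  `"direct"` integrates the multivariate
#' normal density over the continuation rectangles with [mvtnorm::pmvnorm()]
#' (deterministic Miwa algorithm, suitable for the supported `K <= 20`).
#' Either method may serve any number of stages; the Markov recursion is the
#' default because it is fast enough to sit inside the annealing loop.
#'
#' @param method `"markov"` or `"direct"`.
#' @param grid_points quadrature nodes per stage for the recursion (>= 32).
#' @param mvn_tolerance absolute tolerance for the direct method (<= 1e-6).
#' @return An object of class `gsd_engine`.
#' @export
engine_config <- function(method = c("markov", "direct"), grid_points = 64L,
                          mvn_tolerance = 1e-7) {
  method <- match.arg(method)
  grid_points <- as.integer(grid_points)
  if (grid_points < 32L) stop("`grid_points` must be at least 32", call. = FALSE)
  if (mvn_tolerance > 1e-6) stop("`mvn_tolerance` must be <= 1e-6", call. = FALSE)
  structure(list(method = method, grid_points = grid_points,
                 mvn_tolerance = mvn_tolerance),
            class = "gsd_engine")
}

#' Correlation between stagewise z-statistics
#'
#' With equal group sizes the information at analysis i is proportional to i,
#' so `Cov(Z_i, Z_j) = sqrt(n_i / n_j) = sqrt(i / j)` for `i <= j`.
#'
#' @param i,j stage indices with `1 <= i <= j <= K`.
#' @param K number of stages.
#' @return The correlation `sqrt(i / j)`.
#' @examples
#' z_covariance(1, 2, K = 2) # 0.7071
#' @export
z_covariance <- function(i, j, K) {
  if (i > j) stop("`i` must not exceed `j`", call. = FALSE)
  if (i < 1 || j > K) stop("stage indices must satisfy 1 <= i <= j <= K",
                           call. = FALSE)
  sqrt(i / j)
}

#' Joint distribution of the stagewise z-statistics
#'
#' Mean vector `delta_c * sqrt(n_i / (2 sigma^2))` (with `delta_c` the effect
#' centred at `delta0`) and correlation matrix `sqrt(i / j)`.
#'
#' @param d a [gs_design()].
#' @param spec a [design_spec()].
#' @param delta treatment effect (uncentred, same units as `delta1`).
#' @return List with `means` and `covariance`.
#' @export
z_statistic_model <- function(d, spec, delta) {
  stopifnot(inherits(d, "gsd_design"), inherits(spec, "gsd_spec"))
  k <- seq_len(d$K)
  info <- k * d$n1 / (2 * spec$sigma^2)
  means <- (delta - spec$delta0) * sqrt(info)
  covariance <- outer(k, k, function(i, j) sqrt(pmin(i, j) / pmax(i, j)))
  list(means = means, covariance = covariance)
}

# Stagewise first-exit probabilities via the selected engine; internal.
exit_probabilities <- function(d, spec, delta, engine) {
  theta <- delta - spec$delta0
  if (engine$method == "markov") {
    .cpp_exit_probs(d$n1, d$f, d$e, theta, spec$sigma, engine$grid_points)
  } else {
    exit_probabilities_direct(d, spec, theta, engine)
  }
}

exit_probabilities_direct <- function(d, spec, theta, engine) {
  K <- d$K
  info <- seq_len(K) * d$n1 / (2 * spec$sigma^2)
  means <- theta * sqrt(info)
  corr <- outer(seq_len(K), seq_len(K),
                function(i, j) sqrt(pmin(i, j) / pmax(i, j)))
  fut <- eff <- numeric(K)
  alg <- mvtnorm::Miwa(steps = 512, checkCorr = FALSE)
  rect <- function(lower, upper, idx) {
    if (length(idx) == 1L)
      return(pnorm(upper, means[1], 1) - pnorm(lower, means[1], 1))
    # clamp sentinels: beyond |z| = 40 the tail mass is zero to double precision
    as.numeric(mvtnorm::pmvnorm(
      lower = pmax(lower, -40), upper = pmin(upper, 40), mean = means[idx],
      corr = corr[idx, idx, drop = FALSE], algorithm = alg))
  }
  for (i in seq_len(K)) {
    idx <- seq_len(i)
    cont_lo <- d$f[seq_len(i - 1)]
    cont_hi <- d$e[seq_len(i - 1)]
    eff[i] <- if (d$e[i] == Inf && i < K) 0 else
      rect(c(cont_lo, d$e[i]), c(cont_hi, Inf), idx)
    fut[i] <- if (d$f[i] == -Inf && i < K) 0 else
      rect(c(cont_lo, -Inf), c(cont_hi, d$f[i]), idx)
  }
  list(futility = fut, efficacy = eff)
}

#' Probability of rejecting the null hypothesis
#'
#' Sums the probabilities of crossing the efficacy boundary at each stage
#' after continuing through all earlier stages.  At `delta = delta0` this is
#' the attained type I error; at `delta = delta1` the attained power.
#'
#' @inheritParams z_statistic_model
#' @param engine an [engine_config()].
#' @return A probability.
#' @examples
#' spec <- design_spec(1, delta1 = 1, sigma = 3, alpha = 0.05, beta = 0.1)
#' d <- gs_design(155, f = qnorm(0.95), e = qnorm(0.95))
#' rejection_probability(d, spec, delta = 0) # 0.05
#' @export
rejection_probability <- function(d, spec, delta, engine = engine_config()) {
  stop_if_invalid(d)
  sum(exit_probabilities(d, spec, delta, engine)$efficacy)
}

#' Stagewise stopping probabilities
#'
#' Probability of first exit at each analysis, split by direction.  The 2K
#' probabilities sum to one.
#'
#' @inheritParams rejection_probability
#' @return List with length-K vectors `futility` and `efficacy`.
#' @export
stage_stopping_probabilities <- function(d, spec, delta,
                                         engine = engine_config()) {
  stop_if_invalid(d)
  exit_probabilities(d, spec, delta, engine)
}

#' Expected sample size per arm
#'
#' `E[N] = sum_i n_i P(first exit at analysis i)`, with the final-stage
#' sample size weighted by the probability of reaching the final analysis, so
#' interim sentinels (`-Inf`/`Inf`) are handled exactly.
#'
#' @inheritParams rejection_probability
#' @return Expected patients per arm, between `n1` and `K * n1`.
#' @export
expected_sample_size <- function(d, spec, delta, engine = engine_config()) {
  stop_if_invalid(d)
  if (engine$method == "markov")
    return(.cpp_expected_n(d$n1, d$f, d$e, delta - spec$delta0, spec$sigma,
                           engine$grid_points))
  p <- exit_probabilities(d, spec, delta, engine)
  stopped <- p$futility + p$efficacy
  K <- d$K
  if (K == 1) return(d$n1)
  sum(seq_len(K - 1) * d$n1 * stopped[-K]) +
    K * d$n1 * (1 - sum(stopped[-K]))
}

#' Worst-case treatment effect and maximum expected sample size
#'
#' The expected sample size, as a function of the treatment effect, rises to
#' a single maximum and then falls; a golden-section search over the bracket
#' `[delta0, delta0 + 2 (delta1 - delta0)]` therefore locates the worst-case
#' effect with about a dozen evaluations.  If the maximiser lands on a
#' bracket edge the bracket is widened automatically (with a warning).
#'
#' @inheritParams rejection_probability
#' @param bracket optional numeric length-2 search interval for `delta`.
#' @param tol bracket width at which the search stops (effect-size units).
#' @return List with `delta_star` and `e_max`.
#' @export
worst_case_delta <- function(d, spec, engine = engine_config(),
                             bracket = NULL, tol = 1e-4) {
  stop_if_invalid(d)
  if (d$K == 1L) # one-stage trials have constant sample size
    return(list(delta_star = spec$delta0, e_max = d$n1))
  if (is.null(bracket))
    bracket <- c(spec$delta0, spec$delta0 + 2 * (spec$delta1 - spec$delta0))
  if (engine$method == "markov") {
    res <- .cpp_emax(d$n1, d$f, d$e, spec$sigma, engine$grid_points,
                     bracket[1] - spec$delta0, bracket[2] - spec$delta0, tol)
    if (isTRUE(res$widened))
      warning("worst-case search bracket was widened to contain the maximum",
              call. = FALSE)
    return(list(delta_star = res$delta_star + spec$delta0, e_max = res$e_max))
  }
  en <- function(delta) expected_sample_size(d, spec, delta, engine)
  golden_max(en, bracket[1], bracket[2], tol = tol)
}

# Golden-section maximisation with automatic bracket widening; internal.
golden_max <- function(fn, lo, hi, tol = 1e-4, max_widen = 6) {
  gr <- (sqrt(5) - 1) / 2
  for (attempt in seq_len(max_widen)) {
    a <- lo; b <- hi
    c <- b - gr * (b - a); d <- a + gr * (b - a)
    fc <- fn(c); fd <- fn(d)
    while (b - a > tol) {
      if (fc > fd) {
        b <- d; d <- c; fd <- fc
        c <- b - gr * (b - a); fc <- fn(c)
      } else {
        a <- c; c <- d; fc <- fd
        d <- a + gr * (b - a); fd <- fn(d)
      }
    }
    x <- (a + b) / 2
    span <- hi - lo
    if (x > hi - 0.02 * span) {
      hi <- hi + 2 * span
      warning("worst-case search bracket was widened to contain the maximum",
              call. = FALSE)
    } else if (x < lo + 0.02 * span) {
      lo <- lo - 2 * span
      warning("worst-case search bracket was widened to contain the maximum",
              call. = FALSE)
    } else {
      return(list(delta_star = x, e_max = fn(x)))
    }
  }
  list(delta_star = x, e_max = fn(x))
}

#' Full operating-characteristics report
#'
#' Attained type I error and power, stagewise stopping probabilities at the
#' null and the CRD, expected sample sizes at both effects, and the
#' worst-case effect with its maximum expected sample size.
#'
#' @inheritParams rejection_probability
#' @return An object of class `gsd_oc` (a list).
#' @export
operating_characteristics <- function(d, spec, engine = engine_config()) {
  stop_if_invalid(d)
  p0 <- exit_probabilities(d, spec, spec$delta0, engine)
  p1 <- exit_probabilities(d, spec, spec$delta1, engine)
  en <- function(p) {
    stopped <- p$futility + p$efficacy
    K <- d$K
    if (K == 1) return(d$n1)
    sum(seq_len(K - 1) * d$n1 * stopped[-K]) + K * d$n1 * (1 - sum(stopped[-K]))
  }
  wc <- worst_case_delta(d, spec, engine)
  structure(list(
    alpha_attained = sum(p0$efficacy),
    power_attained = sum(p1$efficacy),
    stop_prob_futility = p0$futility,
    stop_prob_efficacy = p0$efficacy,
    e_null = en(p0),
    e_crd = en(p1),
    delta_star = wc$delta_star,
    e_max = wc$e_max,
    max_n = d$K * d$n1,
    design = d, spec = spec
  ), class = "gsd_oc")
}

#' @export
print.gsd_oc <- function(x, ...) {
  cat(sprintf("Operating characteristics (K = %d, n1 = %g, max N = %g per arm)\n",
              x$design$K, x$design$n1, x$max_n))
  cat(sprintf("  attained alpha = %.4f, attained power = %.4f\n",
              x$alpha_attained, x$power_attained))
  cat(sprintf("  E[N] at delta0 = %.1f, at delta1 = %.1f\n", x$e_null, x$e_crd))
  cat(sprintf("  worst-case delta* = %.3f with E_max = %.1f\n",
              x$delta_star, x$e_max))
  invisible(x)
}

#' Expected-sample-size curve over a grid of treatment effects
#'
#' @param designs a named list of [gs_design()] objects (or a single design).
#' @param spec a [design_spec()].
#' @param deltas grid of treatment effects; defaults to the null to twice the
#'   CRD in steps of 0.02 effect units.
#' @param engine an [engine_config()].
#' @return A `data.frame` with column `delta` and one `E[N]` column per design.
#' @export
en_curve <- function(designs, spec, deltas = NULL, engine = engine_config()) {
  if (inherits(designs, "gsd_design")) designs <- list(design = designs)
  if (is.null(deltas))
    deltas <- seq(spec$delta0, spec$delta0 + 2 * (spec$delta1 - spec$delta0),
                  by = 0.02)
  out <- data.frame(delta = deltas)
  for (nm in names(designs))
    out[[nm]] <- vapply(deltas, function(dd)
      expected_sample_size(designs[[nm]], spec, dd, engine), numeric(1))
  out
}
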