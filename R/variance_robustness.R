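#' Boundary correction for analysis with estimated variance
#'
#' When the analysis replaces the known-variance z-statistic by the pooled
#' two-sample t-statistic, each stopping threshold `b` at analysis i is
#' mapped through the normal tail probability to the Student-t quantile with
#' `2 n_i - 2` degrees of freedom: `b~ = T^{-1}_{2 n_i - 2}(Phi(b))`.  The
#' marginal stagewise stopping probabilities under the null then equal the
#' design's nominal ones whatever the true variance; only the joint
#' distribution across stages is approximated.
#'
#' @param d a [gs_design()] whose cumulative sample sizes satisfy
#'   `n_i >= 2`.
#' @return A `gsd_design` with both boundary vectors replaced by their
#'   t-quantile counterparts.
#' @examples
#' modified_boundaries(gs_design(41, f = c(0, 1.96), e = c(2.5, 1.96)))
#' @export
modified_boundaries <- function(d) {
  stopifnot(inherits(d, "gsd_design"))
  df <- 2 * seq_len(d$K) * d$n1 - 2
  if (any(df < 2))
    stop("modified boundaries require at least 2 patients per arm at each analysis",
         call. = FALSE)
  gs_design(d$n1, f = qt(pnorm(d$f), df), e = qt(pnorm(d$e), df))
}

#' Simulate a single trial path
#'
#' Draws `n1` normally distributed responses per arm per stage (treatment
#' mean `delta_true`, control mean 0, common SD `sigma_true`), computes the
#' cumulative test statistic at each analysis — `"z"` uses the design value
#' of sigma, `"t"` and `"t_modified"` the pooled variance estimate from all
#' `2 n_i` observations — and applies the design's (or, for
#' `"t_modified"`, the t-corrected) stopping boundaries.
#'
#' This is the readable patient-level reference; [estimate_error_rates()]
#' runs the same model vectorised over many replicates via its
#' sufficient-statistic reformulation.
#'
#' @param d a [gs_design()] with integer `n1 >= 2`.
#' @param spec a [design_spec()] (supplies the design sigma and `delta0`).
#' @param delta_true,sigma_true true effect and outcome SD generating the
#'   data.
#' @param method `"z"`, `"t"` or `"t_modified"`.
#' @return List with `stage`, `direction` (`"futility"`/`"efficacy"`),
#'   `n_realized` (per arm), `estimates` (cumulative effect estimates up to
#'   exit) and `statistics` (test statistics up to exit).
#' @export
simulate_trial <- function(d, spec, delta_true, sigma_true,
                           method = c("z", "t", "t_modified")) {
  method <- match.arg(method)
  stop_if_invalid(d)
  stopifnot(sigma_true > 0)
  n1 <- as.integer(round(d$n1))
  bounds <- if (method == "t_modified") modified_boundaries(d) else d
  trt <- ctl <- numeric(0)
  est <- stat <- numeric(0)
  for (i in seq_len(d$K)) {
    trt <- c(trt, rnorm(n1, mean = delta_true, sd = sigma_true))
    ctl <- c(ctl, rnorm(n1, mean = 0, sd = sigma_true))
    ni <- i * n1
    dhat <- mean(trt) - mean(ctl)
    sd_use <- if (method == "z") spec$sigma else
      sqrt((sum((trt - mean(trt))^2) + sum((ctl - mean(ctl))^2)) / (2 * ni - 2))
    z <- (dhat - spec$delta0) * sqrt(ni / (2 * sd_use^2))
    est <- c(est, dhat); stat <- c(stat, z)
    if (z > bounds$e[i] || i == d$K && z > bounds$f[i])
      return(list(stage = i, direction = "efficacy", n_realized = ni,
                  estimates = est, statistics = stat))
    if (z <= bounds$f[i])
      return(list(stage = i, direction = "futility", n_realized = ni,
                  estimates = est, statistics = stat))
  }
  # unreachable for valid designs (final boundaries coincide); guard anyway
  list(stage = d$K, direction = "futility", n_realized = d$K * n1,
       estimates = est, statistics = stat)
}

#' Monte-Carlo type I error / power under variance misspecification
#'
#' Vectorised simulation of many trials.  Per replicate, arm and stage the
#' group sum and within-group sum of squares are drawn from their exact
#' sampling distributions (`N(n1 mu, n1 sigma^2)` and
#' `sigma^2 chi^2_{n1 - 1}`), which reproduces the distribution of the
#' cumulative z- and pooled-t statistics exactly without storing individual
#' responses.
#'
#' @inheritParams simulate_trial
#' @param replicates number of simulated trials.
#' @param seed optional integer; when supplied the result is reproducible
#'   (the global RNG is seeded).
#' @return An object of class `gsd_sim_result`: `replicates`, `rejections`,
#'   `type_i_or_power` (rejection proportion), `mc_se` (binomial standard
#'   error) and `mean_sample_size` per arm.
#' @examples
#' d <- gs_design(63, f = c(0, 0.9, 1.7), e = c(2.5, 2.1, 1.7))
#' spec <- design_spec(3, delta1 = 1, sigma = 3, alpha = 0.05, beta = 0.1)
#' estimate_error_rates(d, spec, delta_true = 0, sigma_true = 3,
#'                      method = "z", replicates = 1000, seed = 1)
#' @export
estimate_error_rates <- function(d, spec, delta_true, sigma_true,
                                 method = c("z", "t", "t_modified"),
                                 replicates, seed = NULL) {
  method <- match.arg(method)
  stop_if_invalid(d)
  stopifnot(sigma_true > 0, replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  n1 <- as.integer(round(d$n1))
  if (method != "z" && n1 < 2)
    stop("t-based analysis requires n1 >= 2", call. = FALSE)
  bounds <- if (method == "t_modified") modified_boundaries(d) else d
  R <- as.integer(replicates)
  K <- d$K

  sum_t <- sum_c <- ssq_t <- ssq_c <- numeric(R)
  active <- rep(TRUE, R)
  reject <- logical(R)
  n_real <- rep(K * n1, R)
  for (i in seq_len(K)) {
    # accrue one group per arm (drawn for all replicates to keep the RNG
    # stream independent of earlier stopping decisions)
    st <- rnorm(R, n1 * delta_true, sqrt(n1) * sigma_true)
    sc <- rnorm(R, 0, sqrt(n1) * sigma_true)
    sum_t <- sum_t + st
    sum_c <- sum_c + sc
    if (method != "z") {
      qt_ <- sigma_true^2 * rchisq(R, n1 - 1) + st^2 / n1
      qc_ <- sigma_true^2 * rchisq(R, n1 - 1) + sc^2 / n1
      ssq_t <- ssq_t + qt_
      ssq_c <- ssq_c + qc_
    }
    ni <- i * n1
    dhat <- (sum_t - sum_c) / ni
    if (method == "z") {
      s2 <- spec$sigma^2
    } else {
      s2 <- (ssq_t - sum_t^2 / ni + ssq_c - sum_c^2 / ni) / (2 * ni - 2)
    }
    z <- (dhat - spec$delta0) * sqrt(ni / (2 * s2))
    up <- active & z > bounds$e[i]
    if (i == K) { # final boundaries coincide: reject iff above them
      reject[active] <- z[active] > bounds$e[i]
      active[active] <- FALSE
    } else {
      down <- active & z <= bounds$f[i]
      reject[up] <- TRUE
      n_real[up | down] <- ni
      active <- active & !up & !down
    }
    if (!any(active)) break
  }
  p_hat <- mean(reject)
  structure(list(
    replicates = R, rejections = sum(reject), type_i_or_power = p_hat,
    mc_se = sqrt(p_hat * (1 - p_hat) / R), mean_sample_size = mean(n_real),
    method = method, delta_true = delta_true, sigma_true = sigma_true,
    seed = seed), class = "gsd_sim_result")
}

#' @export
print.gsd_sim_result <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo error-rate estimate (%s analysis, delta = %g, true sigma = %g)\n",
    x$method, x$delta_true, x$sigma_true))
  cat(sprintf("  rejection proportion = %.4f (MC SE %.4f, %d replicates)\n",
              x$type_i_or_power, x$mc_se, x$replicates))
  cat(sprintf("  mean sample size per arm = %.1f\n", x$mean_sample_size))
  invisible(x)
}

#' Error rates over a grid of true standard deviations
#'
#' Runs [estimate_error_rates()] for each combination of analysis method and
#' true sigma, at the null effect (type I error) and at the CRD (power).
#'
#' @inheritParams estimate_error_rates
#' @param sigma_grid true standard deviations to simulate.
#' @param methods analysis methods to include.
#' @return A `data.frame` with columns `sigma_true`, one type I error and
#'   one power column per method.
#' @export
error_rate_table <- function(d, spec, sigma_grid,
                             methods = c("z", "t", "t_modified"),
                             replicates = 50000, seed = NULL) {
  out <- data.frame(sigma_true = sigma_grid)
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  k <- 0L
  for (m in methods) {
    t1 <- pw <- numeric(length(sigma_grid))
    for (j in seq_along(sigma_grid)) {
      s1 <- if (is.null(base_seed)) NULL else (base_seed + (k <- k + 1L))
      t1[j] <- estimate_error_rates(d, spec, spec$delta0, sigma_grid[j], m,
                                    replicates, seed = s1)$type_i_or_power
      s2 <- if (is.null(base_seed)) NULL else (base_seed + (k <- k + 1L))
      pw[j] <- estimate_error_rates(d, spec, spec$delta1, sigma_grid[j], m,
                                    replicates, seed = s2)$type_i_or_power
    }
    out[[paste0("type_i_", m)]] <- t1
    out[[paste0("power_", m)]] <- pw
  }
  out
}
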