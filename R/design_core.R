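#' Specify a group-sequential design problem
#'
#' A design specification fixes what the trial must achieve: `K` analyses, a
#' one-sided test of H0: delta <= `delta0` against the alternative, power at
#' the clinically relevant difference (CRD) `delta1`, outcome standard
#' deviation `sigma`, and error probabilities `alpha` (type I) and `beta`
#' (type II).  All treatment effects are mean differences between arms in
#' outcome units; internally every computation centres the effect at `delta0`,
#' so the default `delta0 = 0` is without loss of generality.
#'
#' @param K integer number of analyses (stages), `K >= 1`.
#' @param delta1 clinically relevant difference; must exceed `delta0`.
#' @param sigma outcome standard deviation, `> 0`.
#' @param alpha maximal type I error probability, in (0, 1).
#' @param beta maximal type II error probability, in (0, 1).
#' @param delta0 null treatment effect (default 0).
#'
#' @return An object of class `gsd_spec`.
#' @examples
#' design_spec(K = 5, delta1 = 1, sigma = 3, alpha = 0.05, beta = 0.1)
#' @export
design_spec <- function(K, delta1, sigma, alpha, beta, delta0 = 0) {
  K <- as.integer(K)
  if (length(K) != 1L || is.na(K) || K < 1L)
    stop("`K` must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(delta1) || !is.numeric(delta0) || delta1 <= delta0)
    stop("`delta1` must exceed `delta0`", call. = FALSE)
  if (!is.numeric(sigma) || sigma <= 0)
    stop("`sigma` must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1)
    stop("`alpha` and `beta` must lie strictly in (0, 1)", call. = FALSE)
  structure(
    list(K = K, delta0 = delta0, delta1 = delta1, sigma = sigma,
         alpha = alpha, beta = beta),
    class = "gsd_spec"
  )
}

#' @export
print.gsd_spec <- function(x, ...) {
  cat(sprintf(
    "Group-sequential design problem: K = %d stages\n  H0: delta <= %g vs CRD delta1 = %g (sigma = %g)\n  alpha = %g, power >= %g at delta1\n",
    x$K, x$delta0, x$delta1, x$sigma, x$alpha, 1 - x$beta))
  invisible(x)
}

#' Single-stage (fixed-sample) sample size per arm
#'
#' The smallest integer `n` per arm for which the one-stage z-test has type I
#' error at most `alpha` and power at least `1 - beta` at `delta1`:
#' the ceiling of `2 * sigma^2 * (z_{1-alpha} + z_{1-beta})^2 / (delta1 -
#' delta0)^2`.  This quantity anchors the whole machinery: it is the default
#' penalty scale `mu` of the annealing objective and the smallest maximum
#' sample size considered by the admissible frontier.
#'
#' @param spec a [design_spec()].
#' @return Integer patients per arm.
#' @examples
#' single_stage_n(design_spec(2, delta1 = 1, sigma = 3, alpha = 0.05, beta = 0.1)) # 155
#' @export
single_stage_n <- function(spec) {
  stopifnot(inherits(spec, "gsd_spec"))
  tau <- spec$delta1 - spec$delta0
  n <- 2 * spec$sigma^2 * (qnorm(1 - spec$alpha) + qnorm(1 - spec$beta))^2 / tau^2
  as.integer(ceiling(n - 1e-9))
}

#' Construct a group-sequential design
#'
#' A design is parameterised by the group size `n1` (patients per arm per
#' stage; the cumulative sample size at analysis i is `i * n1` per arm) and
#' the futility (`f`) and efficacy (`e`) boundary vectors on the z-statistic
#' scale.  At analysis i the trial stops for efficacy if `Z_i > e[i]` and for
#' futility if `Z_i <= f[i]`; the final boundaries coincide (`e[K] == f[K]`)
#' so the trial always ends with a decision.  Infinite sentinels are allowed
#' at interim looks (`f[i] = -Inf`: no futility stop; `e[i] = Inf`: no
#' efficacy stop).
#'
#' The constructor performs only structural checks; use [validate_design()]
#' for the full validity report.  `n1` may be non-integer (the annealing
#' search treats it as continuous before rounding).
#'
#' @param n1 group size per arm per stage, `> 0`.
#' @param f futility boundaries, length `K`.
#' @param e efficacy boundaries, length `K`.
#' @return An object of class `gsd_design`.
#' @examples
#' gs_design(90, f = c(0.2, 1.7), e = c(2.4, 1.7))
#' @export
gs_design <- function(n1, f, e) {
  if (length(f) != length(e))
    stop("`f` and `e` must have the same length", call. = FALSE)
  if (length(n1) != 1L || !is.numeric(n1))
    stop("`n1` must be a single number", call. = FALSE)
  structure(
    list(n1 = as.numeric(n1), f = as.numeric(f), e = as.numeric(e),
         K = length(f)),
    class = "gsd_design"
  )
}

#' @export
print.gsd_design <- function(x, digits = 4, ...) {
  cat(sprintf("Group-sequential design: K = %d, n1 = %s per arm (max N = %s)\n",
              x$K, format(x$n1, digits = digits),
              format(x$K * x$n1, digits = digits)))
  b <- rbind(futility = x$f, efficacy = x$e)
  colnames(b) <- paste0("stage", seq_len(x$K))
  print(round(b, digits))
  invisible(x)
}

#' Validate a group-sequential design
#'
#' Checks the design invariants: `n1 > 0`, `e[k] > f[k]` at every interim
#' analysis, and `e[K] == f[K]` at the final one.  Returns a report rather
#' than raising, so callers (e.g. the annealing proposal loop) can decide how
#' to react.
#'
#' @param d a [gs_design()].
#' @param K expected number of stages; defaults to the design's own length.
#' @return A list with elements `valid` (logical) and `errors` (character).
#' @examples
#' validate_design(gs_design(40, f = c(-0.24, 1.56), e = c(3.01, 1.56)))
#' @export
validate_design <- function(d, K = NULL) {
  stopifnot(inherits(d, "gsd_design"))
  errors <- character()
  if (!is.null(K) && d$K != K)
    errors <- c(errors, sprintf("design has %d stages, expected %d", d$K, K))
  if (!is.finite(d$n1) || d$n1 <= 0)
    errors <- c(errors, "group size n1 must be positive")
  k <- d$K
  if (k > 1L) {
    bad <- which(d$e[-k] <= d$f[-k])
    if (length(bad))
      errors <- c(errors, sprintf(
        "efficacy boundary must exceed futility boundary before the final stage (stage %s)",
        paste(bad, collapse = ", ")))
  }
  if (is.finite(d$e[k]) || is.finite(d$f[k])) {
    if (!isTRUE(abs(d$e[k] - d$f[k]) <= 1e-8))
      errors <- c(errors, "final boundaries must coincide (e[K] == f[K])")
  } else if (!identical(d$e[k], d$f[k])) {
    errors <- c(errors, "final boundaries must coincide (e[K] == f[K])")
  }
  list(valid = length(errors) == 0L, errors = errors)
}

stop_if_invalid <- function(d, K = NULL) {
  rep <- validate_design(d, K)
  if (!rep$valid)
    stop("invalid design: ", paste(rep$errors, collapse = "; "), call. = FALSE)
  invisible(d)
}

#' Read or write a design as JSON
#'
#' Designs serialize as `{"K": ..., "n1": ..., "f": [...], "e": [...]}`.
#'
#' @param d a [gs_design()].
#' @param path file path.
#' @return `read_design()` returns a `gsd_design`; `write_design()` returns
#'   `path` invisibly.
#' @export
write_design <- function(d, path) {
  stopifnot(inherits(d, "gsd_design"))
  jsonlite::write_json(
    list(K = d$K, n1 = d$n1, f = d$f, e = d$e),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gs_design(x$n1, f = as.numeric(x$f), e = as.numeric(x$e))
}

#' One-row data frame of design parameters
#'
#' Column order `n1, f1, e1, f2, e2, ...`, convenient for building parameter
#' tables across designs and for CSV export.
#'
#' @param d a [gs_design()].
#' @return A one-row `data.frame`.
#' @export
design_to_row <- function(d) {
  stopifnot(inherits(d, "gsd_design"))
  vals <- c(d$n1, as.vector(rbind(d$f, d$e)))
  names(vals) <- c("n1", as.vector(rbind(paste0("f", seq_len(d$K)),
                                         paste0("e", seq_len(d$K)))))
  as.data.frame(as.list(vals))
}
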