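#' The nonsymmetric triangular design
#'
#' Constructs the group-sequential triangular design for `K` equally spaced
#' analyses.  On the score scale (`S_k = Z_k * sqrt(I_k)`, information
#' `I_k = k n1 / (2 sigma^2)` per arm) the continuous-monitoring boundaries
#' are the straight lines `u(V) = a + cV` (efficacy) and `l(V) = -a + 3cV`
#' (futility), whose slopes are in the 1:3 ratio characteristic of the
#' triangular test and which satisfy `a * c = -log(2 alpha) / 2`, the
#' relation that fixes the type I error of the symmetric test.  The
#' nonsymmetric extension (`beta != alpha`) rescales the reference effect to
#' `theta~ = 2 z_{1-alpha} (delta1 - delta0) / (z_{1-alpha} + z_{1-beta})`
#' — the effect at which the symmetric test's (approximately linear on the
#' z-scale) power curve passes through `1 - beta` — giving `c = theta~ / 4`
#' and `a = -2 log(2 alpha) / theta~`.
#'
#' Discrete monitoring is handled by the "Christmas-tree" adjustment: each
#' boundary is pulled inward by `0.583 * sqrt(dI)` at every look, including
#' the last, and the final information level `I_K` sits at the apex of the
#' *adjusted* boundaries (`c I_K + 0.583 sqrt(dI) = a`), so the z-scale
#' boundaries converge exactly (`e_K = f_K`).  Solving the apex equation
#' for the per-look information gives the required group size, which is
#' rounded up to an integer; the slope `c` is then recalibrated to the
#' integer group size through the same apex equation (keeping
#' `a * c = -log(2 alpha) / 2`).  Because of the rescaling and the rounding,
#' the attained type I error and power are close to, but not exactly, the
#' nominal values — the defining property of the nonsymmetric triangular
#' design.  Unlike the annealed optimal designs the construction is
#' immediate.
#'
#' @param spec a [design_spec()] with `K >= 2`.
#' @return A [gs_design()] with integer group size; the score-scale
#'   parameters are attached as attribute `"triangular_params"` (list with
#'   `intercept` `a`, `slope_upper` `c`, `slope_lower` `3c` and the per-look
#'   `adjustment`).
#' @examples
#' spec <- design_spec(5, delta1 = 1, sigma = 3, alpha = 0.05, beta = 0.1)
#' triangular_design(spec)
#' @export
triangular_design <- function(spec) {
  stopifnot(inherits(spec, "gsd_spec"))
  K <- spec$K
  if (K < 2L)
    stop("the triangular design requires K >= 2 analyses", call. = FALSE)
  ac <- -log(2 * spec$alpha) / 2
  if (ac <= 0)
    stop("triangular construction requires alpha < 0.5", call. = FALSE)
  za <- qnorm(1 - spec$alpha); zb <- qnorm(1 - spec$beta)
  theta_ref <- 2 * za * (spec$delta1 - spec$delta0) / (za + zb)
  c0 <- theta_ref / 4
  a0 <- ac / c0
  # per-look information from the adjusted-apex equation
  # c0 * K * dI + 0.583 * sqrt(dI) = a0, solved for sqrt(dI)
  u <- (-0.583 + sqrt(0.583^2 + 4 * K * c0 * a0)) / (2 * K * c0)
  n1 <- as.integer(ceiling(2 * spec$sigma^2 * u^2 - 1e-9))
  triangular_for_group_size(spec, n1, ac)
}

# Triangular boundaries for a fixed group size; internal.
triangular_for_group_size <- function(spec, n1, ac) {
  K <- spec$K
  dI <- n1 / (2 * spec$sigma^2)
  adj <- 0.583 * sqrt(dI)
  IK <- K * dI
  # apex of the adjusted boundaries: c * IK + adj = a = ac / c
  cc <- (-adj + sqrt(adj^2 + 4 * IK * ac)) / (2 * IK)
  a <- ac / cc
  info <- seq_len(K) * dI
  e <- (a + cc * info - adj) / sqrt(info)
  f <- (-a + 3 * cc * info + adj) / sqrt(info)
  f[K] <- e[K] # equal at the apex by construction; tie exactly
  d <- gs_design(n1, f, e)
  attr(d, "triangular_params") <- list(intercept = a, slope_upper = cc,
                                       slope_lower = 3 * cc, adjustment = adj)
  d
}

#' Operating characteristics of the triangular design
#'
#' Convenience composition of [triangular_design()] and
#' [operating_characteristics()].
#'
#' @inheritParams triangular_design
#' @param engine an [engine_config()].
#' @return A `gsd_oc` report.
#' @export
triangular_oc <- function(spec, engine = engine_config()) {
  operating_characteristics(triangular_design(spec), spec, engine)
}
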