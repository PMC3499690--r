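#' Loss balancing maximum expected and maximum sample size
#'
#' `loss = p * e_max + (1 - p) * max_n`.  `p = 0` weights only the maximum
#' sample size (the minimax criterion); `p = 1` only the maximum expected
#' sample size (the delta-minimax criterion).
#'
#' @param e_max maximum expected sample size per arm.
#' @param max_n maximum sample size per arm.
#' @param p weight in `[0, 1]`.
#' @return The loss (vectorised over its arguments).
#' @export
design_loss <- function(e_max, max_n, p) {
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  p * e_max + (1 - p) * max_n
}

#' Frontier of minimum-E_max designs at each maximum sample size
#'
#' For each candidate maximum sample size per arm — starting from the
#' single-stage sample size rounded up to a multiple of `K` and stepping by
#' `K` so the group size stays integer — a boundary-only annealing search
#' finds the feasible design minimising the maximum expected sample size.
#' Each search warm-starts from the previous entry's boundaries.  The
#' enumeration stops when the optimised `E_max` no longer decreases, i.e.
#' when the delta-minimax design has been reached (any larger trial has both
#' a larger maximum and a larger maximum expected sample size).  Candidate
#' sizes at which no feasible design exists are skipped.
#'
#' @param spec a [design_spec()] with `K >= 2`.
#' @param sa a [sa_config()] for the boundary-only searches.
#' @param engine an [engine_config()].
#' @param max_n_start optional first maximum sample size per arm (multiple
#'   of `K`).
#' @param max_entries safety cap on the number of frontier entries.
#' @return An object of class `gsd_frontier`: a `data.frame` with one row
#'   per entry (`max_n`, `n1`, `e_null`, `e_max`, `e_crd`, `delta_star`,
#'   `alpha`, `power`, `ratio_single_stage`) and the designs in attribute
#'   `"designs"`.  Entries are not yet flagged for admissibility; see
#'   [admissible_set()].
#' @export
design_frontier <- function(spec, sa = sa_config(), engine = engine_config(),
                            max_n_start = NULL, max_entries = 50L) {
  stopifnot(inherits(spec, "gsd_spec"))
  K <- spec$K
  if (K < 2L) stop("the frontier requires K >= 2", call. = FALSE)
  ss_n <- single_stage_n(spec)
  if (is.null(sa$mu)) sa$mu <- ss_n
  if (is.null(sa$t_c1)) sa$t_c1 <- 0.1 * ss_n
  max_n <- if (is.null(max_n_start)) K * ceiling(ss_n / K) else max_n_start
  if (max_n %% K != 0)
    stop("`max_n_start` must be a multiple of K", call. = FALSE)

  rows <- list(); designs <- list(); warm <- NULL; skipped <- 0L
  while (length(rows) < max_entries) {
    # warm start from the previous entry's boundaries; the first entry starts
    # from the triangular design's boundary shape at the requested group size
    init <- if (is.null(warm)) {
      d0 <- initial_design(spec)
      gs_design(max_n / K, d0$f, d0$e)
    } else {
      gs_design(max_n / K, warm$f, warm$e)
    }
    fit <- tryCatch(
      run_sa(spec, "minimax", sa = sa, engine = engine, initial = init,
             fix_n1 = TRUE),
      error = function(e) NULL)
    if (is.null(fit)) { # infeasible at this maximum sample size: step up
      skipped <- skipped + 1L
      if (length(rows) == 0L && skipped > 20L)
        stop("no feasible design found at any candidate maximum sample size",
             call. = FALSE)
      if (length(rows) > 0L) break
      max_n <- max_n + K
      next
    }
    if (length(rows) > 0L) {
      prev <- rows[[length(rows)]]
      if (fit$e_max >= prev$e_max - sa$improvement_tolerance) break
    }
    d <- fit$design
    rows[[length(rows) + 1L]] <- data.frame(
      max_n = max_n, n1 = d$n1,
      e_null = expected_sample_size(d, spec, spec$delta0, engine),
      e_max = fit$e_max,
      e_crd = expected_sample_size(d, spec, spec$delta1, engine),
      delta_star = fit$delta_star, alpha = fit$alpha, power = fit$power,
      ratio_single_stage = max_n / ss_n)
    designs[[length(designs) + 1L]] <- d
    warm <- d
    max_n <- max_n + K
  }
  # descending refinement sweep: the early entries start cold (their feasible
  # sets are tightest), so re-optimise each one warm-started from the entry
  # above it and keep the better result
  for (i in rev(seq_len(length(rows) - 1L))) {
    init <- gs_design(rows[[i]]$max_n / K, designs[[i + 1L]]$f,
                      designs[[i + 1L]]$e)
    fit <- tryCatch(
      run_sa(spec, "minimax", sa = sa, engine = engine, initial = init,
             fix_n1 = TRUE),
      error = function(e) NULL)
    if (!is.null(fit) && fit$e_max < rows[[i]]$e_max) {
      d <- fit$design
      rows[[i]] <- data.frame(
        max_n = rows[[i]]$max_n, n1 = d$n1,
        e_null = expected_sample_size(d, spec, spec$delta0, engine),
        e_max = fit$e_max,
        e_crd = expected_sample_size(d, spec, spec$delta1, engine),
        delta_star = fit$delta_star, alpha = fit$alpha, power = fit$power,
        ratio_single_stage = rows[[i]]$max_n / ss_n)
      designs[[i]] <- d
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "designs") <- designs
  attr(out, "spec") <- spec
  class(out) <- c("gsd_frontier", class(out))
  out
}

#' Identify admissible designs and their p-intervals
#'
#' A frontier entry is admissible when it minimises
#' `p * e_max + (1 - p) * max_n` over the frontier for some weight `p`;
#' geometrically, when it lies on the lower-left convex hull of the
#' `(max_n, e_max)` points.  Each admissible entry receives the interval of
#' weights for which it is the best design, obtained from the pairwise loss
#' equality with its hull neighbours: consecutive hull points `(x1, y1)`,
#' `(x2, y2)` tie at `p = (x2 - x1) / ((x2 - x1) + (y1 - y2))`.  The
#' intervals of the admissible entries partition `[0, 1]`; the entry with
#' the smallest maximum sample size owns `p = 0` (the minimax design) and
#' the delta-minimax entry owns `p = 1`.  Collinear hull points are kept as
#' admissible with degenerate adjacent intervals.
#'
#' @param frontier a [design_frontier()] result (or any data frame with
#'   columns `max_n` and `e_max`, sorted or not).
#' @return The input with columns `admissible`, `p_low` and `p_high`
#'   appended (`NA` interval for inadmissible entries).
#' @export
admissible_set <- function(frontier) {
  df <- as.data.frame(frontier)
  if (!all(c("max_n", "e_max") %in% names(df)))
    stop("`frontier` must have columns `max_n` and `e_max`", call. = FALSE)
  n <- nrow(df)
  ord <- order(df$max_n, df$e_max)
  x <- df$max_n[ord]; y <- df$e_max[ord]
  df$admissible <- FALSE
  df$p_low <- NA_real_; df$p_high <- NA_real_
  if (n == 1L) {
    df$admissible <- TRUE; df$p_low <- 0; df$p_high <- 1
    return(restore_frontier(df, frontier))
  }
  # lower convex hull by monotone chain (keep collinear points)
  hull <- integer()
  for (i in seq_len(n)) {
    while (length(hull) >= 2L) {
      a <- hull[length(hull) - 1L]; b <- hull[length(hull)]
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross < -1e-12) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  # keep only the strictly decreasing part of the hull (up to the E_max min)
  ymin_at <- which.min(y[hull])
  hull <- hull[seq_len(ymin_at)]
  m <- length(hull)
  pb <- numeric(0)
  if (m > 1L) {
    i1 <- hull[-m]; i2 <- hull[-1L]
    pb <- (x[i2] - x[i1]) / ((x[i2] - x[i1]) + (y[i1] - y[i2]))
  }
  lows <- c(0, pb); highs <- c(pb, 1)
  idx <- ord[hull]
  df$admissible[idx] <- TRUE
  df$p_low[idx] <- lows
  df$p_high[idx] <- highs
  restore_frontier(df, frontier)
}

restore_frontier <- function(df, frontier) {
  attr(df, "designs") <- attr(frontier, "designs")
  attr(df, "spec") <- attr(frontier, "spec")
  if (inherits(frontier, "gsd_frontier"))
    class(df) <- c("gsd_frontier", class(df))
  df
}

#' @export
print.gsd_frontier <- function(x, digits = 2, ...) {
  cat("Design frontier (minimum E_max at each maximum sample size per arm)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
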