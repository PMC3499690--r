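---
title: "Optimal multistage group-sequential designs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal multistage group-sequential designs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gsminimax)
```

## The trial model

`gsminimax` designs two-arm randomised trials with normally distributed
outcomes (common standard deviation $\sigma$), analysed at $K$ equally spaced
looks: the $i$-th analysis happens after $n_i = i\,n_1$ patients per arm.  The
one-sided hypothesis is $H_0:\delta \le \delta_0$ for the mean difference
$\delta$, with type I error at most $\alpha$ and power at least $1-\beta$ at
the clinically relevant difference (CRD) $\delta_1$.  At look $i$ the
cumulative z-statistic $Z_i = \hat\delta_i \sqrt{n_i/(2\sigma^2)}$ is compared
with a futility boundary $f_i$ (stop, fail to reject) and an efficacy boundary
$e_i$ (stop, reject); $e_K = f_K$, so the trial always ends with a decision.
All internal computation centres the effect at $\delta_0$, so the default
$\delta_0 = 0$ loses no generality.

The vector $(Z_1,\dots,Z_K)$ is multivariate normal with means
$\delta\sqrt{n_i/(2\sigma^2)}$, unit variances and
$\mathrm{Cov}(Z_i,Z_j) = \sqrt{n_i/n_j}$.  Every quantity the package reports
— attained $\alpha'$, power, stagewise stopping probabilities, expected sample
size $E[N](\delta)$ — is an integral of that density over continuation
rectangles.

## Two independent probability engines

Two numerically independent routes compute those integrals, and their
agreement is part of the test suite:

* **Markov recursion** (`engine_config("markov")`, the default).  On the
  score scale $S_k = Z_k\sqrt{I_k}$ the increments are independent normals,
  so the continuation sub-density propagates look by look.  Each continuation
  interval is discretised with Gauss–Legendre quadrature (`grid_points`
  nodes, default 64) after truncation at 8 conditional standard deviations;
  the truncated mass is below $10^{-14}$, and 64 nodes give agreement with
  the direct method to well under $10^{-5}$.  The recursion is implemented in
  C++ because it sits inside the annealing loop (a single operating
  characteristic costs microseconds).
* **Direct integration** (`engine_config("direct")`).  Each stagewise exit
  probability is a multivariate-normal rectangle probability evaluated by
  `mvtnorm::pmvnorm` with the deterministic Miwa algorithm.  This route is
  slower but shares no code with the recursion, which is what makes it a
  useful cross-check; either engine may serve any $K$.

A third, Monte-Carlo route (direct simulation of the score increments, and
the patient-level simulator of the variance-robustness module) provides the
distribution-level oracle in the tests.

## Worst-case effect and the $\delta$-minimax criterion

$E[N](\delta)$ rises to a single maximum and falls again, because the
probability of stopping early for efficacy increases with $\delta$ while the
probability of stopping for futility decreases.  `worst_case_delta()`
exploits that unimodality with a golden-section search on
$[\delta_0,\ \delta_0 + 2(\delta_1-\delta_0)]$ (the bracket widens itself,
with a warning, if the maximiser touches an edge; termination at a bracket
width of $10^{-4}$ effect units gives $E_{\max}$ well inside 0.01 patients).
The $\delta$-minimax design minimises $E_{\max} = \max_\delta E[N](\delta)$
over feasible designs; the null-optimal and CRD-optimal designs minimise
$E[N](\delta_0)$ and $E[N](\delta_1)$.

## Simulated annealing

`run_sa()` minimises the penalised objective
$f(d) = \text{base}(d) + \mu\left[\tfrac{(\alpha'-\alpha)_+}{\alpha} +
\tfrac{(\beta'-\beta)_+}{\beta}\right]$, where base is $E_{\max}$ or a
fixed-$\delta$ expected sample size.  The penalty is zero exactly on the
feasible set, continuous at its boundary, and scales violations relative to
their targets so that a violation comparable to its target costs about
$\mu$ patients; $\mu$ defaults to the single-stage sample size
(`single_stage_n()`), large enough that infeasible basins never win.  Both
the penalty's normalised-linear form and the common cooling factor for all
three temperatures are package choices (configurable), made because
violations of very different scales ($\alpha$ vs $\beta$) must be comparable.

Each iteration perturbs the current design with independent Gaussian noise —
variance `t_c1` on $n_1$ (default: 10% of the single-stage sample size) and
`t_c2 = 3` on each of the $2K-1$ free boundary coordinates — redrawing until
$n_1 > 0$ and $e_k > f_k$; a worse candidate is accepted with probability
$\exp(-\Delta/t_a)$, $t_a = 100$ initially.  All three temperatures shrink by
$\rho = 0.999$ per iteration and reset at each block of 10 000 iterations.

Three scheduling choices matter in practice and were validated empirically:

* **Triangular warm start.**  The default initial design is the closed-form
  triangular design (below): it is immediate to construct and lies next to
  the $\delta$-minimax family.  A generic interpolated-boundary start leaves
  the chain, for $K \ge 3$, in the basin of a design that never stops early
  (a disguised single-stage trial), a strong local optimum.
* **Elitist block restarts.**  Each block restarts the chain from the best
  design found so far.  Restarting from the chain's final state re-scrambles
  during the hot phase and blocks stop improving immediately.
* **Refinement blocks.**  After the full-temperature blocks stop improving
  (by less than `improvement_tolerance`, default 0.01 patients), blocks at
  temperatures divided by $\sqrt{100}$ and then $100$ polish the last
  fraction of a patient; a refinement phase ends after two consecutive
  non-improving blocks.

Because $n_1$ varies continuously in phase one, a second phase rounds it to
the nearest integer and re-anneals the boundaries only.  The chain's
incumbent is the penalised best, but the returned design is the best
design seen that is feasible at the final-check tolerance: the penalised optimum sits marginally inside
the infeasible region (a first-order trade of a tiny violation against
expected sample size), so returning it would silently violate the error
constraints.  A final check recomputes $\alpha'$ and power and errors out
(reporting both) if no feasible design was found.

The objective landscape is extremely flat in $n_1$ near the optimum: for the
two-stage $\delta$-minimax problem at $(\alpha,\beta) = (0.05, 0.1)$,
$\delta_1 = 1$, $\sigma = 3$, the per-$n_1$ optimal $E_{\max}$ at
$n_1 = 88, 89, 90, 91$ are 133.304, 133.302, 133.297, 133.351 — ties to
within 0.006 patients.  Different runs therefore legitimately return
different group sizes (and hence maximum sample sizes) at essentially
identical objective values; comparisons of annealed designs should be made
on the objective, not coordinate by coordinate.

## The triangular design

On the score scale the triangular test's continuation region is bounded by
$u(V) = a + cV$ and $l(V) = -a + 3cV$, with $a c = -\log(2\alpha)/2$ (the
symmetric test's type I error relation).  For $\beta \ne \alpha$ the
reference effect is rescaled to
$\tilde\theta = 2 z_{1-\alpha}(\delta_1-\delta_0)/(z_{1-\alpha}+z_{1-\beta})$,
giving $c = \tilde\theta/4$.  Discrete monitoring applies the
"Christmas-tree" adjustment $0.583\sqrt{\Delta I}$ at every look (including
the last), and the final information level sits at the apex of the adjusted
boundaries, so the z-scale boundaries converge exactly.  Solving the apex
equation gives the required group size, which is rounded **up** to an
integer; the slope is then recalibrated to the integer group size through the
same apex equation.  The attained error rates are deliberately *not* exact
(e.g. $\alpha' = 0.0517$ at $K = 2$, $0.0512$ at $K = 3$ for the default
scenario) — that inexactness is the known price of the nonsymmetric
extension, and the package reports it rather than re-tuning the boundaries.

## Admissible designs

For each candidate maximum sample size (starting at the single-stage sample
size rounded up to a multiple of $K$, stepping by $K$ so the group size stays
integer), `design_frontier()` runs a boundary-only anneal minimising
$E_{\max}$, warm-starting each search from the previous entry's boundaries,
and stops when $E_{\max}$ no longer decreases — the $\delta$-minimax design
has been reached.  A descending refinement sweep then revisits each entry
warm-started from the entry above it, keeping the better result: the
smallest maximum sample sizes have the tightest feasible sets and benefit
most from a second, better-informed start.  `admissible_set()` marks the entries on the lower convex
hull of $(\max N, E_{\max})$ as admissible and assigns each the interval of
weights $p$ for which it minimises the loss $p\,E_{\max} + (1-p)\max N$;
interval endpoints come from pairwise loss equality of neighbouring hull
points.  Collinear hull points are kept, with degenerate adjacent intervals.
The loss's weighted-sum form is validated in the tests by reproducing the
published case-study interval boundaries from the published table entries.

One honest caveat, documented rather than hidden: for the case-study
scenario ($\delta_1 = 1$, $\sigma = 2.3$, $\alpha = 0.025$, $\beta = 0.2$,
$K = 2$) an independent grid search shows the true optimal $E_{\max}$ at
per-arm maximum sample sizes 84 and 86 to be 77.13 and 74.37 — slightly
better than the published 77.38 and 74.96, while entries 88–96 agree to
$\le 0.03$.  A well-converged frontier therefore yields a first $p$-interval
boundary near 0.42 rather than the published 0.453; the published value is
consistent with the published (sub-optimal) pair, and reproducing it would
require deliberately under-optimising the first two entries.

## Unknown variance

The design assumes $\sigma$ known; `estimate_error_rates()` quantifies what
happens when the truth differs.  Three analysis rules are simulated: the
z-test with the design $\sigma$; the pooled t-test (variance estimated from
all $2n_i$ observations, $2n_i - 2$ df); and the t-test with
`modified_boundaries()`, which maps each threshold $b_i$ to
$T^{-1}_{2n_i-2}(\Phi(b_i))$ so the marginal stagewise error under the null
is preserved whatever the true variance (only the cross-stage correlation
remains approximate).  The simulator draws per-arm, per-stage group sums and
within-group sums of squares from their exact sampling distributions — an
exact sufficient-statistic reformulation of patient-level simulation, not an
approximation — so 250 000-replicate runs take seconds.  A readable
patient-level `simulate_trial()` is kept as the reference implementation and
the two are checked against each other and against the numerical engines.

## Synthetic designs for property tests

`fixture_designs()` generates structurally valid random designs with
monotone boundary shapes (efficacy decreasing to, futility increasing to, a
common final value).  They emulate the geometry of real group-sequential
boundaries — which is all the engine-equivalence, unimodality and
monotonicity properties need — but are not constrained to be feasible or
optimal, so passing those tests says nothing about error-rate control of any
particular fixture, only about the correctness of the probability machinery.

## Problem sizes and numerical choices

Defaults: 64 quadrature nodes per stage; Miwa MVN integration with absolute
tolerance $10^{-7}$; golden-section tolerance $10^{-4}$ on the effect scale;
annealing blocks of 10 000 iterations with $\rho = 0.999$, refinement factor
100, improvement tolerance 0.01 patients.  The test-suite and
reproduction-script problem sizes are chosen to keep full runs in minutes on
one core: the two-stage optimisation and the case-study frontier run at
full block size, the variance-robustness tables at 50 000 replicates
(250 000 in the reproduction script, matching the published precision of
about $\pm 0.001$), and the engine-equivalence sweep at 100 random designs
per stage count.  Ties at the 0.005-patient level (see the flat-valley note
above), the 2 d.p. rounding of published boundaries, and Monte-Carlo error
at the stated replicate counts set the meaningful comparison tolerances used
throughout the tests.

## Limitations

Binary outcomes, unequal allocation, unequal group sizes, two-sided tests,
error-spending constructions, sample-size re-estimation and the exact joint
distribution of sequential t-statistics are out of scope.  Stage counts
above 5 are accepted but not validated against published values, and
annealing becomes less reliable as the dimension grows — for large $K$,
several seeds should be compared on the objective.
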