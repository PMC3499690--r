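# gsminimax

Design machinery for two-arm group-sequential randomised trials with
continuous (normal) outcomes and stopping for futility or efficacy at every
interim analysis — aimed at trial statisticians choosing multistage designs
for phase II settings.

A design with $K$ analyses is parameterised by the group size $n_1$
(patients per arm per stage) and z-scale boundary vectors
$(f_1,\dots,f_K)$, $(e_1,\dots,e_K)$ with $e_K = f_K$: at look $i$ the
cumulative statistic $Z_i = \hat\delta_i\sqrt{n_i/(2\sigma^2)}$ stops the
trial for efficacy if $Z_i > e_i$ or futility if $Z_i \le f_i$.  The package

* computes **exact operating characteristics** — attained $\alpha'$, power,
  stagewise stopping probabilities, $E[N](\delta)$ and its maximum
  $E_{\max} = \max_\delta E[N](\delta)$ — by two independent engines
  (a C++ Markov recursion over the z-statistic sequence, and direct
  multivariate-normal integration via `mvtnorm`);
* finds **optimal designs by simulated annealing**: null-optimal
  ($\min E[N](\delta_0)$), CRD-optimal ($\min E[N](\delta_1)$) and
  **δ-minimax** ($\min E_{\max}$), under the constraints
  $\alpha' \le \alpha$, power $\ge 1-\beta$ via a penalised objective;
* constructs the nonsymmetric **triangular design** in closed form
  (score-scale straight-line boundaries with the discrete-monitoring
  adjustment);
* enumerates **admissible designs** trading off $E_{\max}$ against the
  maximum sample size — the convex-hull frontier with the $p$-interval of
  weights for which each design minimises
  $p\,E_{\max} + (1-p)\max(N)$; and
* quantifies **robustness to variance misspecification** by Monte-Carlo
  simulation of z-test, t-test and t-quantile-corrected analyses.

## Worked example

Evaluate the published five-stage δ-minimax design for the scenario
$\delta_0 = 0$, $\delta_1 = 1$, $\sigma = 3$, $\alpha = 0.05$,
$\beta = 0.1$:

```r
library(gsminimax)
spec <- design_spec(K = 5, delta1 = 1, sigma = 3, alpha = 0.05, beta = 0.1)
d <- gs_design(41, f = c(-0.52, 0.34, 0.92, 1.38, 1.83),
                   e = c( 2.54, 2.09, 2.03, 1.96, 1.83))
operating_characteristics(d, spec)
#> Operating characteristics (K = 5, n1 = 41, max N = 205 per arm)
#>   attained alpha = 0.0499, attained power = 0.8999
#>   E[N] at delta0 = 89.1, at delta1 = 102.1
#>   worst-case delta* = 0.581 with E_max = 119.6
```

A single-stage trial for the same requirements needs
`single_stage_n(spec)` = 155 patients per arm; the sequential design caps
enrolment at 205 per arm but expects at most 119.6 even at the least
favourable treatment effect.  To search for a two-stage δ-minimax design
from scratch and compare it with the closed-form triangular design:

```r
spec2 <- design_spec(K = 2, delta1 = 1, sigma = 3, alpha = 0.05, beta = 0.1)
set.seed(1)
fit <- run_sa(spec2, "minimax")   # a few minutes
fit$e_max                         # ~133.3 (attained alpha 0.0500, power 0.9000)
triangular_oc(spec2)$e_max        # 132.2, but attained alpha' = 0.0517
```

A thin command-line front end over the same functions is installed at
`exec/gsminimax` (subcommands `oc`, `optimize`, `triangular`, `admissible`,
`simulate-variance`, `fixtures`), reading and writing designs as JSON and
reports as JSON/CSV.

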