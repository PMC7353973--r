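---
title: "Methods: two-patch consumer-resource dynamics with fitness-directed movement"
author: "crmove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-patch consumer-resource dynamics with fitness-directed movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmove)
```

## The model

`crmove` studies a consumer population exploiting a sedentary resource
across two patches of unequal quality. Resources grow logistically; the
consumer takes them through a Type I (linear) functional response and moves
between patches. Writing $R_i$, $C_i$ for the resource and consumer
densities in patch $i \in \{H, L\}$,

$$\frac{dR_i}{dt} = r_i R_i \left(1 - \frac{R_i}{K_i}\right) - \alpha R_i C_i,$$

$$\frac{dC_H}{dt} = p\,(c \alpha R_H - \mu)\,C_H + C_L Q_{HL} - C_H Q_{LH},$$

and symmetrically for $C_L$. Consumer fitness is the local per-capita
growth rate, $w_i = c \alpha R_i - \mu$, and the per-capita movement rate
from patch $j$ into patch $i$ is

$$Q_{ij} = \beta\, e^{\lambda (w_i - w_j)}.$$

Two traits of the mover are thus separated: **mobility** $\beta$, the
baseline rate of patch switching, and **fitness sensitivity** $\lambda$,
how strongly that switching is biased toward the patch offering higher
fitness. The binary switch $p$ turns consumer demography on ($p = 1$) or
off ($p = 0$); with it off, consumers change patches but their total
$C_H + C_L = 2 C_T$ is conserved, isolating the behavioural (movement)
timescale from the demographic one. A third movement regime ties the two
traits linearly, $\lambda = \gamma \beta$ with $\gamma > 0$, modelling
animals whose higher mobility also buys them better information about
patch quality.

Assumptions worth keeping in view: the two patches are equal in size;
resources do not move; the functional response never saturates and
consumers do not interfere; all consumers are identical. The package
restricts itself to parameter regions with positive equilibrium densities
in both patches and to parameter sets with stable equilibria — oscillatory
regimes are out of scope.

### Parameters, units, defaults

| symbol | meaning | units | captioned default |
|---|---|---|---|
| $r_H, r_L$ | resource intrinsic growth rates | 1/time | 2, 1 |
| $K_H, K_L$ | resource carrying capacities | density | 100, 50 |
| $\alpha$ | attack rate | 1/(consumer·time) | 0.05 |
| $c$ | conversion efficiency | — | 0.05 |
| $\mu$ | consumer mortality | 1/time | 0.1 |
| $\beta$ | mobility | 1/time | swept |
| $\lambda$ | fitness sensitivity | time | swept |
| $\gamma$ | $\lambda/\beta$ ratio | time² | 0.1, 1, 10 |
| $C_T$ | mean consumer density per patch ($p=0$) | density | 15 |

The patch labelled `high` is, by convention, the one with the larger $r$
and $K$; violating the convention is a warning, not an error, because the
equations are symmetric under relabelling (a property the test suite
checks).

## Equilibria

**Demography on, no movement** ($p = 1$, $\beta = 0$): the patches
decouple into independent Lotka–Volterra systems with logistic prey. The
resource is pinned where fitness vanishes, $R^* = \mu / (c\alpha)$ — the
same in both patches — and $C_i^* = (r_i/\alpha)(1 - \mu/(c\alpha K_i))$.
`equilibrium_no_movement()` evaluates these closed forms and errors if
$\mu/(c\alpha) \ge K_i$ (consumer persistence fails, leaving the model's
positive-density regime).

**Demography off** ($p = 0$): the unique positive equilibrium balances the
migration fluxes, $C_L Q_{HL} = C_H Q_{LH}$, equivalently

$$\frac{C_L^*}{C_H^*} = e^{-2\lambda c \alpha (R_H^* - R_L^*)},
\qquad R_i^* = K_i\!\left(1 - \frac{\alpha C_i^*}{r_i}\right).$$

Mobility $\beta$ cancels out of these conditions: it sets the pace of
convergence but not the destination. `equilibrium_no_demography()` solves
them in log-ratio form,
$g(C_H) = \ln\frac{2C_T - C_H}{C_H} + 2\lambda c\alpha\,(R_H(C_H) -
R_L(2C_T - C_H))$, which is strictly decreasing in $C_H$ (its derivative
is $-(1/C_H + 1/C_L) - 2\lambda c \alpha^2 (K_H/r_H + K_L/r_L) < 0$), so a
bracketed `uniroot` on $(\varepsilon,\, 2C_T - \varepsilon)$,
$\varepsilon = 10^{-12} C_T$, is unconditionally convergent; a few Newton
steps with the analytic derivative then polish the root to machine
precision. A bracket without a sign change, or a non-positive resource at
the root, means the parameters left the positive-density regime and is an
error, not a silent clip.

At $\lambda = 0$ the solution is the equal split $C_H^* = C_L^* = C_T$; as
$\lambda \to \infty$ the resource gap closes like
$|R_H^* - R_L^*| = \ln(C_H^*/C_L^*) / (2\lambda c \alpha)$ and the
fitnesses equalize — the ideal free distribution. That $1/\lambda$ scaling
fixes what "large $\lambda$" buys: with the default parameters the fitness
gap is below $10^{-4}$ at $\lambda = 10^4$, but pushing the *resource* gap
below $10^{-3}$ takes $\lambda \gtrsim 3 \times 10^5$ (the tests use
$10^6$).

**General case** ($p = 1$, $\beta > 0$): no closed form.
`equilibrium_numeric()` runs a damped Newton iteration (backtracking line
search on the residual max-norm) on the derivative field with a
finite-difference Jacobian, to a residual tolerance of $10^{-11}$ — just
above the rounding floor of the finite-difference linear solve at the
model's density scale of $O(10^2)$ — and guarantees $10^{-10}$ or raises.
For $p = 0$ the fourth equation is replaced by the conservation constraint
$C_H + C_L = 2C_T$, which pins the otherwise one-parameter family of
equilibria to the guess's conservation class. Two failure modes are
handled explicitly rather than papered over:

* *non-convergence* — the guess is relaxed by integrating the ODE to the
  default horizon and Newton is retried from the endpoint;
* *boundary roots* — the system has saddle equilibria with a resource
  extinct (e.g. strong mixing with near-zero sensitivity drains the
  low-quality patch in the Newton basin of a naive guess). A converged
  root with any component below $10^{-6}$ is treated like non-convergence
  and re-solved from the relaxed guess, which lies in the interior
  attractor's basin. A genuinely negative converged component raises.

`equilibrium_integrate()` (the endpoint of a horizon-5000 integration) is
kept as an independent oracle: it follows the flow instead of solving the
algebra, and `run_sweep()` cross-checks a seeded random 10% of its rows
against it at $10^{-6}$.

## Stability

Stability is classified from the eigenvalues of a Jacobian obtained by
central finite differences of the implemented right-hand side (step
$h = 10^{-6}\max(1, |x_j|)$), not from hand-derived entries — the
classification then cannot drift out of sync with the equations, and the
test suite validates the finite differences against the analytic logistic
linearizations ($r_i$ at extinction, $-r_i$ at carrying capacity). With
$p = 0$ the conserved consumer total makes one direction of the full 4-D
linearization structurally neutral, so stability is assessed on the 3-D
reduced system with $C_L$ eliminated; the reported
`eigen_real_parts` has length 3 there and 4 otherwise. Every equilibrium
the shipped parameter sets produce is classified stable, matching the
regime the package restricts itself to.

## Scenarios, sweeps and their defaults

`run_sweep()` drives four scenarios: sensitivity swept with demography off
(`vary_lambda_p0`), mobility swept at fixed sensitivity
(`vary_beta_fixed_lambda_p1`), sensitivity swept at fixed mobility
(`vary_lambda_fixed_beta_p1`), and covarying movement (`covary_p1`,
$\lambda = \gamma\beta$). The shipped presets fix the levels at
$\lambda \in \{0.1, 10, 1000\}$, $\beta \in \{0.01, 0.1, 1\}$ and
$\gamma \in \{0.1, 1, 10\}$ respectively, with the captioned demographic
parameters above.

Axis ranges are the package's own choice (the source analyses state none):
sensitivity grids use 50 log-spaced points on $[0.01, 20]$ with 0
prepended — wide enough to show both the equal-split intercept and the IFD
plateau; mobility grids use 50 evenly spaced points on $[0, 10]$
(covarying sweeps start at 0.2, just above zero, since $\beta = 0$ is
covered exactly by the closed form and the interesting structure is
interior). Within a level, the Newton solver is warm-started by
continuation from the previous grid point, which keeps it on the interior
branch.

Two derived summaries matter:

* `regional_resource_trend()` — with demography off, whether the regional
  (mean) resource density rises, falls or stays constant as sensitivity
  grows is decided entirely by the between-patch comparison of the
  density-dependent mortality coefficient $r/K$: equal ratios leave it
  invariant, a larger ratio in the high-quality patch makes it rise
  (consumers relocating there relieve proportionally more intraspecific
  competition), a smaller one makes it fall. The sweep's `mean_R` column
  verifies the prediction numerically.
* `disparity_profile()` — the between-patch differences $C_H^* - C_L^*$
  and $R_H^* - R_L^*$ along a sweep, with each series' extremum located on
  the grid and, when interior, refined by golden-section search on the
  continuous equilibrium map (`stats::optimize`), because the covarying
  scenario's turning point is a property of the continuous map, not of any
  grid. A minimum sitting on the first grid point of a $(0, b]$ grid still
  counts as interior (the domain is open at 0) and is refined downward.
  Under covarying movement the consumer disparity is unimodal in $\beta$:
  random mixing dominates at low movement and erodes the disparity, while
  the co-rising sensitivity dominates at higher movement and rebuilds it;
  with the shipped parameters and $\gamma = 10$ the refined minimum sits
  near $\beta \approx 0.16$, well below the reversal bound of 2 the
  headline check asserts.

`time_to_equilibrium()` quantifies the convergence-speed role of mobility
in the $p = 0$ setting: it integrates from a deliberately unequal split
(consumers 90/10, resources at $K/2$ — an equal split would make the
transient degenerate) and reports the first time the relative max-norm
distance to the known equilibrium falls below $\varepsilon = 10^{-3}$ and
stays there. Early times are sampled at $\Delta t = 0.01$ so that
high-mobility convergence is resolved. At $\lambda = 0$ the consumer
subsystem decouples and the gap decays exactly as $e^{-2\beta t}$, which
the tests check against the closed form.

## Numerical choices and degenerate inputs

* **Integration** — `deSolve::ode`, method `lsoda` (stiff-capable;
  sensitivity values up to $10^3$ make the movement terms stiff), relative
  tolerance $10^{-10}$, absolute $10^{-12}$. Simulations run to a horizon
  of 5000 time units, read as continuous model time; the shipped parameter
  sets settle well within it.
* **Exponent clamping** — the movement exponent $\lambda(w_i - w_j)$ is
  clamped to $\pm 700$ before exponentiation. Unclamped, $\lambda = 10^3$
  with an order-one fitness gap overflows a double; the clamp preserves
  sign and (weak) monotonicity, and is inactive anywhere near equilibrium,
  where fitness gaps are small.
* **Negative densities** — the derivative field is a total function (no
  clipping), so it can be finite-differenced across the axes; instead the
  integrator's output is monitored and any component below $-10^{-6}$
  raises. That threshold separates genuine misuse from the $O(10^{-12})$
  jitter the tolerances permit around zero.
* **"Resembling the immobile equilibrium"** — the extreme-sensitivity
  sweep levels off at an equilibrium close to, but not exactly at, the
  $\beta = 0$ closed forms: with the default parameters the $p = 1$,
  $\lambda = 1000$ equilibrium has $C_L^* = 4.120$ against the immobile
  4.000, essentially independent of $\beta > 0$ (the two independent
  solvers agree). The package therefore quantifies the resemblance
  relative to each species' larger patch density (scale 40 for resources,
  24 for consumers), under which the deviation is below 1%; relative to
  the small $C_L^*$ component alone it is 3%, a genuine finite-$\lambda$
  offset, not solver error.
* **Output formatting** — all CSV output renders numerics with `%.12g`:
  reproducible byte-identical files without hiding tolerance-level drift.
* **Determinism** — the only randomness anywhere is the sweep
  cross-check's subsample (default seed 20200247, restored on exit).

## Problem sizes

The shipped defaults — 50-point grids, three levels per scenario, horizon
5000 — were chosen so that a full preset sweep (150 equilibria with
continuation plus the seeded cross-check) completes in a few seconds and
the entire test suite in well under a minute, while still resolving every
asymptote and turning point the summaries assert.

## Known limitations

Two patches only, equal in size; sedentary resources; Type I functional
response without interference. Oscillatory/cyclic parameter regimes are
excluded by design — the stability classifier will dutifully report such
equilibria unstable, but the package offers no limit-cycle analysis.
Travel costs, movement delays, social information and between-individual
heterogeneity in movement traits are outside the model. The covariation
rule is linear; other monotone links between mobility and sensitivity
would slot into `apply_covary()` but are not implemented.
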