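# crmove

Two-patch consumer–resource dynamics with fitness-directed consumer
movement: a simulator, equilibrium solver and sweep engine for theoretical
ecologists studying how animal movement traits shape consumer and resource
distributions across heterogeneous habitat.

## The model

A consumer exploits a sedentary, logistically growing resource in a
high-quality (H) and a low-quality (L) patch:

    dR_i/dt = r_i R_i (1 − R_i/K_i) − α R_i C_i
    dC_H/dt = p (c α R_H − μ) C_H + C_L Q_HL − C_H Q_LH      (and symmetrically for C_L)

Consumer fitness is the local per-capita growth rate `w_i = c α R_i − μ`,
and movement from patch j into patch i follows the exponential kernel

    Q_ij = β exp(λ (w_i − w_j))

separating **mobility** `β` (baseline switching rate) from **fitness
sensitivity** `λ` (how strongly switching is biased toward the better
patch). The switch `p` turns consumer demography on (`p = 1`) or off
(`p = 0`; consumer total conserved). A covariation rule `λ = γβ` models
movers whose mobility and environmental information rise together.

The package computes equilibria four ways (closed form without movement;
implicit flux-balance solve without demography; damped-Newton root-finding;
long-integration endpoint as an independent cross-check), classifies their
linear stability by numerical eigenvalues, and sweeps mobility, sensitivity
or both to map out the equal-split → ideal-free-distribution transition,
the regional-resource r/K trichotomy, convergence-time scaling, and the
unimodal consumer-disparity pattern under covarying movement.

## Worked example

```r
library(crmove)

pr <- model_params(patch_params(r = 2, K = 100), patch_params(r = 1, K = 50),
                   alpha = 0.05, c = 0.05, mu = 0.1, beta = 1, lam = 0, p = 0)
equilibrium_no_demography(pr, conserved_total(15))
#> Equilibrium (implicit_no_demography)
#>   R_H* = 62.5  R_L* = 12.5
#>   C_H* = 15  C_L* = 15
#>   w_H = 0.05625  w_L = -0.06875
#>   residual = 0, stable (max Re(eig) = -0.25)
```

With no fitness sensitivity (`lam = 0`) movement is pure mixing: consumers
split equally (15 per patch, the conserved mean), leaving the resource —
and hence fitness — much higher in the good patch. Raising the sensitivity
redistributes them:

```r
pr$lam <- 5
equilibrium_no_demography(pr, conserved_total(15))
#> Equilibrium (implicit_no_demography)
#>   R_H* = 50.621576  R_L* = 24.378424
#>   C_H* = 19.75137  C_L* = 10.24863
#>   w_H = 0.026553939  w_L = -0.039053939
#>   residual = 7.11e-15, stable (max Re(eig) = -0.604)
```

Consumers now overmatch the good patch (19.8 vs 10.2) and the fitness gap
has narrowed from 0.125 to 0.066; as `lam` grows further it closes
entirely — the ideal free distribution. With demography on and movement
covarying (`λ = γβ`), the consumer disparity is instead unimodal in β:

```r
cfg <- figure_presets("fig5")   # p = 1, covarying movement
cfg$fixed_levels <- 10          # gamma = lambda / beta
tab  <- run_sweep(cfg)
prof <- disparity_profile(tab, cfg)[["10"]]
round(prof$dC_min_at, 3)
#> [1] 0.155
```

Mixing erodes the demographic disparity up to β ≈ 0.155, after which the
co-rising sensitivity rebuilds it. `figure_presets()` ships all the
standard parameter sets (`fig1`–`fig5`); the methods vignette
(`vignettes/crmove-methods.Rmd`) documents the model, solvers and every
numerical choice.

## Command line

A thin CLI is installed at `exec/crmove` inside the package (or run
`./exec/crmove` from the source tree):

```sh
crmove presets
crmove equilibrium --preset fig3 --out eq.json
crmove simulate --config run.yaml --out traj.csv
crmove sweep --preset fig5 --out sweep.csv
```

Configs are YAML (JSON accepted) with flat model keys
`r_H, r_L, K_H, K_L, alpha, c, mu, beta, lam, p` (optional `gamma`, top
level `C_T`); unknown keys are rejected. CSV output uses fixed `%.12g`
formatting, so identical configs give byte-identical files.

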