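# lstpgm — latent state-trait piecewise growth models

`lstpgm` is an R package for the measurement side of piecewise
(linear-linear) latent growth models: how much of a repeated measurement
reflects stable trait change, how much reflects transient situational
(state) influences, and how much is noise. It is aimed at psychometric and
longitudinal-methods researchers who model two-phase trajectories — a
learning curve that bends after an intervention, symptom change that
flattens after remission — and want defensible reliability statements
about the indicators they use.

## The models

Both model families share three growth factors — initial level ξ₁, first
change ξ₂−ξ₁, second change ξ₃−ξ₂ — on which occasion j at time t_j loads
through the piecewise basis

    b_j = (1, min(t_j, t_γ), max(t_j − t_γ, 0)),

with the knot t_γ fixed by design. The **SI-PGM** observes one indicator
per occasion, y_t = b_j'ξ + ε_t, and can only define a **reliability**
coefficient: state variance is confounded with error. The **MI-PGM**
observes several indicators per occasion,

    y_it = ω_it + λ_it (b_j'ξ + ζ_t) + ε_it,

where the state residual ζ_t is shared within an occasion; this identifies
the state variance and splits each indicator's variance into

* **consistency** — trait share, λ² b_j'Ψb_j / var(y_it)
* **occasion specificity** — state share, λ² σ²_ζt / var(y_it)
* **reliability** — their sum.

The package provides the implied moment structure of both models,
normal-theory maximum-likelihood estimation from wide-format data, the
coefficients above, a synthetic-data generator whose state and error
variances are calibrated so occasion specificity and reliability hit exact
targets, and a Monte Carlo harness that summarises parameter recovery as
relative bias across a 24-cell factorial design (sample size ×
situational-effect magnitude × analysis model).

## Worked example

```r
library(lstpgm)

# population: 7 occasions coded 0..6, knot at t = 3, two tau-parallel
# indicators, reliability 0.8 of which 0.25 is occasion specificity
gd <- generating_design(target_os = 0.25, target_rel = 0.8)
head(lst_coefficients(gd), 2)
#>   indicator occasion consistency occasion_specificity reliability total_variance
#> 1         1        1        0.55                 0.25         0.8       1.818182
#> 2         2        1        0.55                 0.25         0.8       1.818182

y   <- simulate_pgm(gd, n = 500, seed = 42)   # 500 x 14 wide matrix
fit <- fit_pgm(y)                             # MI-PGM by ML
fit
#> MI-PGM maximum-likelihood fit, n = 500
#>   discrepancy F = 0.203965  logLik = -12687.514
#>   converged: TRUE  ( 29 iterations, max |grad| = 5.83e-07 )
#> growth means:
#>   level change1 change2
#>  9.9982  1.9628  0.9814
```

The fitted growth means sit near the generating values (10, 2, 1); the
discrepancy F is the ML fit function (0 would mean the implied moments
reproduce the sample moments exactly). Fitting the SI-PGM to the same data
means averaging the two indicators first — the composite's true
reliability is the Spearman–Brown step-up `spearman_brown(0.8, 2)` =
0.889 — and its estimated reliability is attenuated by exactly the state
share the single-indicator model cannot see:

```r
ys <- aggregate_indicators(y)
cf <- lst_coefficients(fit_pgm(ys))
mean(cf$reliability)
#> [1] 0.608034     # plim (0.8 - 0.25)/0.9 = 0.611, truth 0.889
```

The full factorial recovery study is one call:

```r
st <- run_study(n_replications = 200, base_seed = 1)
write_results(st, "results")   # table1_growth_bias.csv, table2_reliability_bias.csv, study_log.json
```

A thin command-line wrapper with `simulate` / `fit` / `coeffs` / `study`
subcommands is in `inst/cli/lstpgm.R`.

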