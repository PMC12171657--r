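# epbsim

Simulation of long-run criminal recidivism under incomplete
ascertainment — the "dark figure" of crime. Official statistics count
*charged* reoffenses; `epbsim` models how the cumulative *actual*
reoffending rate relates to the observed one under explicit assumptions
about offending, desistance, and the probability that an offense is ever
charged.

## The model

Each offender's year-1 offense intensity λ₁ is drawn from an Exponential
population with mean μ. In year *i* the offender commits
*Nᵢ* ~ Poisson(λᵢ) offenses, of which *Cᵢ* ~ Binomial(*Nᵢ*, *r*) are
charged, where *r* is the per-offense charge probability. The annual odds
of reoffending, *oᵢ* = e^λᵢ − 1, decline by a fixed fraction *d* per year
through the recurrence

    λ_{i+1} = log(1 + (1 − d)(e^{λ_i} − 1)),

so *o*\_{i+1} = (1 − *d*) *oᵢ* exactly. With *d* = 0.123 the odds are
retained at 0.877 per year, the meta-analytic desistance estimate the
default scenarios use. The population mean μ is calibrated so the
model's 25-year cumulative *charged* rate equals an observed benchmark
(default 18.5%); the model then implies the corresponding *actual* rate.

Conditional on λ₁ the cumulative rates have closed forms via Poisson
thinning — P(actual by *t*) = 1 − e^(−Sₜ) and
P(charged by *t*) = 1 − e^(−*r*Sₜ) with Sₜ = Σ λᵢ — so the package ships
both a vectorised Monte Carlo engine (`run_mc()`, Latin Hypercube
sampling of λ₁ by default) and an exact analytic engine
(`population_rates()`, adaptive quadrature over the Exponential frailty)
that cross-validate each other.

## A worked example

```r
library(epbsim)

cal <- calibrate_mu(r = 0.25, schedule = 0.123)
cal
#> Calibrated population mean: mu = 0.111438 offenses/year
#>   anchor: 25-year charged rate = 0.185 (achieved 0.185)
#>   r = 0.25, d = 0.123, method = analytic, 9 solver iterations

spec <- scenario_spec(cal$mu, r = 0.25, schedule = 0.123,
                      n_iterations = 30000, seed = 20250122)
run_mc(spec)
#> Cumulative reoffending rates (monte_carlo, 30000 iterations)
#>  year actual charged actual_se charged_se
#>     5 0.3089  0.1037  0.002668   0.001760
#>    10 0.4062  0.1505  0.002836   0.002064
#>    15 0.4449  0.1707  0.002869   0.002172
#>    20 0.4629  0.1815  0.002879   0.002225
#>    25 0.4720  0.1880  0.002882   0.002256
```

If only a quarter of offenses result in a charge, a population whose
*observed* 25-year recidivism is 18.8% (within sampling error of the
18.5% anchor) has an *actual* 25-year reoffending rate of 47.2%: the
charged column is what studies can measure, the actual column is what
the model infers.

`replicate_table1()` runs this exercise across seven charge rates,
`replicate_table2()` adds a sensitivity grid over desistance rates
0/5/12.3/20%, and `trajectory_series()` exports per-year population
hazard, probability, and odds series.

## Command line

```sh
Rscript inst/cli/epbsim.R calibrate --r 1.0 --desistance 0.123
Rscript inst/cli/epbsim.R run --mu 0.1123 --r 0.25 --iterations 30000 --out run.json
Rscript inst/cli/epbsim.R table1 --iterations 30000 --out table1.csv
```

Subcommands: `calibrate`, `run`, `table1`, `table2`, `trajectories`.
Tables are written as CSV with a JSON provenance sidecar; exit codes are
0 (ok), 1 (validation), 2 (numerical failure).

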