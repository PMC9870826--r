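# vcusim

Simulation laboratory for **informative drop-out bias in variety-trial
trend estimation**.

Long-running registration ("value for cultivation and use", VCU) trial
series are the main source for separating crop yield trends into a genetic
part (improvement of newly entered genotypes) and a non-genetic part
(agronomy, climate).  The standard decomposition fits the mixed model

    ȳ_ijkl = μ + γ·t_k + Z_k + L_j + β·r_i + H_i
             + (LY)_jk + (LYT)_jkl + (GL)_ij + (GY)_ik + e_ijkl

by REML, where `t_k` is the calendar year of testing, `r_i` the year a
genotype was first tested, `β` the genetic and `γ` the non-genetic trend
slope, and the remaining terms are independent crossed random effects.
Because candidates are culled after their first and second testing year
*based on the analysed trait*, reducing such series — e.g. to genotypes
tested at least three years — creates an informative (MNAR) missingness
pattern that biases variance components and both slopes.  `vcusim`
quantifies this bias by simulation: it generates VCU-like trial skeletons,
simulates phenotypes with zero true trends, reproduces BLUP-based culling,
constructs the reduced dataset variants, re-fits the model with its own
sparse REML solver, and aggregates the bias across runs.

## Worked example

```r
library(vcusim)

# a quarter-scale series: 9 years, 30 locations, ~2,600 observations
params <- vcu_structure_params(scale = 0.25, seed = 7)
st     <- build_structure(params)
st
#> VCU trial structure: 9 years, 7 cycles, 30 locations
#>   2613 cells (1932 candidate, 681 check), 175 trials, 163 genotypes

# one run: simulate with the historical variance components (zero trends),
# select survivors by genotype BLUP, drop candidates tested <= 2 years
sim <- simulate_run(st, bsa_variance_components(), mode = "blup", seed = 99)
d2  <- drop_short_tested(sim$data, 2)
fit <- reml_fit(d2, trend_model_spec(), start = bsa_variance_components())
trend_slopes(fit)
#>       beta      gamma
#>  0.4188048 0.2349032
```

The simulated trends are zero, so the fitted genetic slope of this single
reduced run (+0.42 dt/ha per year at quarter scale) is pure selection
bias.  Averaging across runs gives the systematic picture:

```r
ex <- run_experiment("complete", runs = 4, scale = 0.25, seed = 5)
ex
#> Simulation experiment 'complete': 4 runs, scale 0.25
#>   C    mean obs 2657 | beta -0.026 (-0.403; +0.350) | gamma -0.554 | MSE 1.92 | rank cor 0.753
#>   C-1  mean obs 2171 | beta +0.189 (-0.124; +0.501) | gamma -0.697 | MSE 9.21 | rank cor 0.748
#>   C-2  mean obs 1625 | beta +0.458 (+0.132; +0.785) | gamma -0.772 | MSE 17.86 | rank cor 0.737
```

On complete data (`C`) the genetic trend is unbiased; dropping candidates
tested up to one (`C-1`) or two (`C-2`) years pushes it increasingly
positive, mirrored by the non-genetic slope (the simulated total trend is
zero, so the two biases cancel), while the genotype variance collapses and
the BLUP mean squared error grows.  `run_experiment()` also provides the
`"single-mean"` variant (no duplicate check rows; estimates unbiased), the
`"random-selection"` benchmark (bias vanishes) and the `"inflated-gxy"`
scenario (genotype-by-year variance 55.75; bias grows).

See the vignette `vignettes/informative-dropout.Rmd` for the model,
generator design and numerical choices.

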