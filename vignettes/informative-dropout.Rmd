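---
title: "Quantifying informative drop-out bias in registration-trial trend estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying informative drop-out bias in registration-trial trend estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcusim)
```

## The problem

Official registration ("value for cultivation and use", VCU) trial series
accumulate decades of multi-environment yield data.  Because every cohort of
candidate genotypes is culled after its first and second testing year, and
culling is driven by the measured trait, the long-running dataset contains a
built-in *informative* missingness mechanism: which observations exist
depends on the phenotypes themselves.  Analysts often reduce such series
further — e.g. to genotypes tested at least three years — before separating
the yield trend into a genetic and a non-genetic component.  `vcusim` is a
simulation laboratory for measuring what that reduction does to the variance
components and to the two trend slopes.

## The model

One phenotypic mean per genotype-by-trial combination is modelled as

$$\bar y_{ijkl} = \mu + \gamma t_k + Z_k + L_j + \beta r_i + H_i +
(LY)_{jk} + (LYT)_{jkl} + (GL)_{ij} + (GY)_{ik} + (GLY)_{ijk} + e_{ijkl},$$

where $t_k$ is the calendar year of testing and $r_i$ the year a genotype
was first tested (both uncentered); $\beta$ is the genetic and $\gamma$ the
non-genetic trend; all other terms are independent zero-mean normal random
effects with one variance per factor.  The genotype and year main effects
are decomposed as $G_i = \beta r_i + H_i$ and $Y_k = \gamma t_k + Z_k$, so
$H_i$ and $Z_k$ are deviations from the two trend lines.  The trial effect
$(LYT)$ and the separation of $(GLY)$ from the plot error exist because a
year-by-location combination can host several parallel trial series, and
check varieties appear in each of them — candidates never duplicate within
a year-by-location combination.

The generating variance components (`bsa_variance_components()`) are the
REML estimates from the 1983–2016 German winter wheat registration series
(year 25.13, location 53.15, year-by-location 74.14, trial 8.83, genotype
13.27, genotype-by-year 3.16, genotype-by-location 2.25, three-way 9.62,
error 9.36, all in dt² ha⁻²).  Both trend slopes are simulated as zero, so
every non-zero estimated slope downstream is bias, not signal.

## The trial-structure generator

The historical layout itself is not available, so `build_structure()`
generates skeletons that reproduce its summary geometry rather than its
exact cells; all downstream claims are about expectations over this class
of structures.  The default parameters are the published aggregates: 34
years, a pool of 120 locations, per-cycle entry counts ramping linearly
from 60 to 120, culling fractions 0.51 after year 1 and 0.26 after year 2
(both constant over time; the historical rise of the third-year proportion
is not modelled by default, but `cull_frac_y2` accepts a per-cycle
schedule), series tested at 11/13/24 locations in years 1–3, and expected
within-cycle location overlaps of 2, 1 and 8 (the published means 1.9, 1.3
and 7.6, rounded).  Location sets are drawn by first sampling the pairwise
overlap groups and then topping each series up with disjoint draws, which
hits the expected overlaps exactly without needing the real location map.
No cycle starts after year `n_years - 2`, so every cycle completes and the
survivor arithmetic `round(entries * (1 - cull1))` and
`round(entries * (1 - cull1 - cull2))` is exact.

Checks form a staggered panel: start years spread evenly over the series,
activity spans geometric with mean `check_span_years` (default 7), plus a
repair pass that guarantees at least two active checks per year and a
shared check between consecutive years — the connectivity on which trend
estimation rests (`check_connectivity()`).  With 48 checks averaging 7
active years over 34 calendar years, about ten checks are concurrently
active and appear in *every* trial of their active years; the generated
check observation count (≈15k) therefore sits somewhat above the
historical 13,010, where checks occasionally missed trials.  Candidate
aggregates land within a few percent of the published table (≈66k candidate
observations vs 64,792; 2,884 genotypes vs 2,912).  A check whose activity
starts in year $s \ge 4$ is flagged as a former candidate of the cycle
that finished in year $s-1$: at assembly it takes over the identity of the
best-ranked unused year-3 survivor of that cycle, so its genotype and
genotype-by-location effects continue seamlessly (the explicit effect-copy
semantics are exposed as `transfer_check_effects()`).  Candidates repeating
in a second cycle — frequent historically but mechanism unknown — are not
modelled.

The `scale` argument shrinks designs for desk work: years, location pool,
entries and checks scale linearly; per-series location counts, overlaps
and check spans scale with $\sqrt{\text{scale}}$.  At `scale = 0.25` a
design has 9 years, 30 locations and roughly 2,500–3,000 observations.

## Simulation and selection protocol

Per run (`simulate_run()`), year, location, year-by-location and trial
effects are drawn once and shared by everything; each cycle's *complete*
three-year data are then simulated for all entries.  Survivors into year 2
are the entries with the largest genotype BLUPs from the single-year model
$\bar y_{ij} = \mu + L_j + G_i + e_{ij}$ fitted to the cycle's year-1
trials (checks included), where $G$ absorbs genotype-by-year, $L$ absorbs
year-by-location and trial, and the residual absorbs genotype-by-location,
the three-way term and plot error.  Survivors into year 3 are selected
from the year-2 survivors with the two-year model (year, location,
genotype, year-by-location+trial, genotype-by-location, genotype-by-year;
residual = three-way + error).  Ties in BLUPs are broken by entry id.
Keeping only the selected entries' already-simulated rows is equivalent to
the label-exchange construction (re-assigning genotype labels to survivor
slots): the observed layout is fixed either way.

Two open choices were resolved as follows.  First, the selection fits use
the *true* generating variance components (confounded as above) rather
than per-cycle REML re-estimates: this isolates the selection-induced bias
from small-sample variance noise and makes the selection as sharp as
possible, in line with reading the resulting bias as an upper bound.
Second, a check's genotype-by-year and three-way effects are keyed per
factor level, so duplicate check rows within a year-by-location share
their three-way effect — exactly the covariance that the reduced analysis
model ignores, and the only difference between the complete and
single-mean variants.  One master seed drives a single sequential RNG
stream (shared effects first, then cycles in order), which reproduces a
run exactly; with random-mode selection the draws interleave, so the two
modes are compared across runs, not draw-by-draw.

`drop_short_tested()` removes candidates by distinct tested years (never
touching genotypes with check observations), producing the `-1`/`-2`
variants; `dedup_checks()` keeps one uniformly chosen row per
genotype-year-location, producing the single-mean variant whose analysis
model coincides with the generating model.

## REML implementation

`reml_fit()` maximizes the restricted likelihood of the crossed model with
the residual variance profiled out.  Writing $V = \sigma^2_e(I + \sum_f
\gamma_f Z_f Z_f^\top)$, the criterion reduces to
$\log|M| + \sum_f q_f\log\gamma_f + (n-p)\log\hat\sigma^2_e$ plus
constants, where $M$ is the mixed-model-equation matrix with $1/\gamma_f$
added to the diagonal of factor $f$'s block and $\hat\sigma^2_e =
y^\top(y - W\hat b)/(n-p)$.  Each evaluation is one sparse Cholesky
refactorization (the symbolic analysis and the nonzero pattern are reused;
only diagonal entries change between iterations).  The log variance
ratios are optimized by box-constrained quasi-Newton iteration (`nlminb`,
relative tolerance $10^{-11}$, at most 200 iterations); bounds of
$\pm 18$ on $\log\gamma_f$ implement the non-negativity constraint, and a
ratio at the lower bound is reported as a zero variance with fully shrunk
BLUPs.  Update-based schemes (average-information or EM steps) need the
per-block traces of $M^{-1}$, which a sparse factorization does not yield
cheaply; profiling plus quasi-Newton needs only factorizations and solves,
and on instances small enough for a dense brute-force maximizer the two
agree to $10^{-6}$ in log-likelihood and $10^{-4}$ in the components (the
test suite checks 20 such instances, and cross-checks a larger crossed fit
against `lme4` at matching tolerances).  Default starting values split the
phenotypic variance equally across factors ($\gamma_f = 1$); experiment
drivers start at the generating components, which roughly halves the
iteration count without affecting the optimum at these tolerances.  Fixed
effects and their plain asymptotic standard errors come from
$(X^\top\hat V^{-1}X)^{-1}$ (no small-sample adjustment); genotype
deviation BLUPs come from the same solve.  When a dataset has no duplicate
genotype-year-location rows the separate three-way factor is structurally
unidentifiable and is collapsed into the residual automatically.  A
rank-deficient fixed design — e.g. when every genotype is tested in a
single year so $r_i$ duplicates $t_k$ — raises an estimability error.

## Evaluation and aggregation

Per variant, `run_experiment()` averages variance components and slopes
across runs with normal-approximation 95% intervals (mean ± 1.96 · SE; at
the run counts used the difference from a $t$ interval is negligible).
BLUP accuracy is summarized by the mean squared error between predicted
and realized $H_i$ over genotypes tested at least three distinct years
(checks included), pooled across runs with inverse-squared-standard-error
weights, and by the Spearman rank correlation averaged across runs.

## Problem sizes and test design

The bundled experiments run at `scale = 0.25` (9 years, 30 locations,
about 2,500–3,000 observations per run): 50 runs for the single-mean
unbiasedness check, 50 runs for the BLUP-selection bias block, 25 each for
the random-selection and inflated genotype-by-year scenarios; the
acceptance script uses 30/20/12/12 runs.  These sizes are the package's
own desk-scale choices; the published full-scale magnitudes (e.g. a
genetic-trend bias of +0.11 dt ha⁻¹ year⁻¹ after dropping genotypes tested
up to two years, MSE 1.42 → 8.97 → 16.79) are claimed only at full scale,
which `run_experiment(scale = 1, runs = 500)` reproduces given hours of
compute.  Statistical assertions were fixed before the experiments were
run: directional claims use one-sided $z \ge 2$ on across-run contrasts —
paired within an experiment, where per-run environmental noise cancels —
and coverage claims use Bonferroni-adjusted simultaneous intervals, since
requiring ten separate 95% intervals to cover simultaneously would fail a
correct implementation about 40% of the time.

## What the generator does and does not emulate

Passing tests show that *given* this structure class — overlapping
three-year cycles, shared checks, normal homoscedastic effects,
single-trait BLUP truncation selection — the estimation machinery is
unbiased without informative drop-out and reproduces the documented bias
pattern with it.  Real series differ in ways the generator does not model:
multi-trait selection indices (lower per-trait intensity, hence smaller
bias — the simulated bias is an upper bound), BLUE-based and
second-year-only decisions as actually practised, candidates re-entering
later cycles, temporally varying culling fractions, non-normal or
heteroscedastic effects, spatial within-trial structure, and pedigree or
marker relationships that would link selection across cohorts.  Non-linear
trends are out of scope; the two linear regressions are the estimand.
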