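Package: vcusim
Title: Simulation of Informative Drop-Out Bias in Variety Trial Trend
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how systematic data reduction biases genetic and
    non-genetic trend estimates obtained from historical value-for-cultivation
    -and-use (VCU) variety trial series.  The package generates trial
    skeletons with overlapping three-year testing cycles and long-running
    check varieties, simulates yield data from a crossed linear mixed model,
    reproduces the culling of candidate genotypes by best linear unbiased
    prediction (BLUP) of genotype effects, constructs reduced dataset
    variants (dropping short-tested candidates, de-duplicating check
    observations), re-fits the trend-decomposition mixed model by restricted
    maximum likelihood (REML) with a sparse solver, and aggregates variance
    component, trend-slope, mean-squared-error and rank-correlation summaries
    across simulation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
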