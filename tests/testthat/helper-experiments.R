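# Reduced-scale simulation experiments shared across test files.  They are
# expensive (minutes), so each is run once per session and cached.  All
# seeds and run counts are fixed constants of the test design.
.experiment_cache <- new.env(parent = emptyenv())

get_experiment <- function(name) {
  if (!exists(name, envir = .experiment_cache)) {
    ex <- switch(
      name,
      SM = run_experiment("single-mean", runs = 50, scale = 0.25,
                          seed = 101, variants = 0),
      C  = run_experiment("complete", runs = 50, scale = 0.25, seed = 202),
      RS = run_experiment("random-selection", runs = 25, scale = 0.25,
                          seed = 303),
      I  = run_experiment("inflated-gxy", runs = 25, scale = 0.25,
                          seed = 404),
      stop("unknown experiment ", name)
    )
    assign(name, ex, envir = .experiment_cache)
  }
  get(name, envir = .experiment_cache)
}

# across-run mean and its standard error for one parameter column
run_mean_se <- function(ex, variant, parameter) {
  x <- ex$estimates[[variant]][, parameter]
  c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
}

# paired per-run contrast between two variants of the same experiment
paired_contrast <- function(ex, v1, v2, parameter) {
  d <- ex$estimates[[v1]][, parameter] - ex$estimates[[v2]][, parameter]
  c(mean = mean(d), se = stats::sd(d) / sqrt(length(d)))
}
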