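#' Run a complete simulation experiment
#'
#' Wires the whole pipeline end to end for one scenario: build the trial
#' skeleton once, then per run simulate phenotypes, apply the selection
#' protocol, construct the dataset variants (complete, minus candidates
#' tested one year, minus candidates tested up to two years), fit the
#' reduced trend model by REML, and collect variance components, trend
#' slopes, BLUP mean squared errors and rank correlations across runs.
#'
#' Scenarios:
#' \describe{
#'   \item{`"complete"`}{BLUP-based selection; variants C, C-1, C-2.  The
#'     complete variant retains duplicate check observations, so the
#'     analysis model (three-way interaction confounded with the residual)
#'     differs from the generating model.}
#'   \item{`"single-mean"`}{as `"complete"` but check duplicates are removed
#'     at random first (variants SM, SM-1, SM-2); analysis and generating
#'     model then coincide and estimates are unbiased.}
#'   \item{`"random-selection"`}{survivors drawn uniformly (MCAR benchmark);
#'     variants RS, RS-1, RS-2.}
#'   \item{`"inflated-gxy"`}{BLUP selection with the genotype-by-year
#'     variance raised to 55.75 (variants I, I-1, I-2), probing how the
#'     trend bias scales with the variance that selection acts upon.}
#' }
#'
#' @param scenario one of `"complete"`, `"single-mean"`,
#'   `"random-selection"`, `"inflated-gxy"`.
#' @param runs number of simulation runs.
#' @param scale structure scale passed to [vcu_structure_params()] when
#'   `params` is not given.
#' @param seed master seed; all per-run seeds derive from it.
#' @param params optional explicit [vcu_structure_params()].
#' @param vc optional explicit generating [variance_components()].
#' @param variants which reductions to analyse: subset of `0:2` (0 = no
#'   reduction, k = drop candidates tested in up to k years).
#' @param start_at_truth start the REML iterations at the generating
#'   variance components (halves the iteration count; the convergence
#'   tolerance, not the start, determines the optimum).
#' @param verbose print per-run progress.
#' @return An object of class `vcu_experiment`: per-variant estimate
#'   matrices, across-run summaries ([summarize_runs()]), pooled MSE
#'   ([pooled_mse()]), mean rank correlations, convergence bookkeeping, and
#'   the generating structure/parameters.
#' @export
run_experiment <- function(scenario = c("complete", "single-mean",
                                        "random-selection", "inflated-gxy"),
                           runs = 10, scale = 0.25, seed = 1L,
                           params = NULL, vc = NULL, variants = 0:2,
                           start_at_truth = TRUE, verbose = FALSE) {
  scenario <- match.arg(scenario)
  stopifnot(all(variants %in% 0:2), runs >= 2)
  prefix <- c("complete" = "C", "single-mean" = "SM",
              "random-selection" = "RS", "inflated-gxy" = "I")[[scenario]]
  seeds <- derive_seeds(seed, runs + 1L)
  params <- params %||% vcu_structure_params(scale = scale, seed = seeds[1])
  struct <- build_structure(params)
  vc <- vc %||%
    bsa_variance_components(inflate_genotype_year = scenario == "inflated-gxy")
  mode <- if (scenario == "random-selection") "random" else "blup"
  spec <- trend_model_spec()
  truth <- experiment_truth(vc)
  vnames <- paste0(prefix, c("", "-1", "-2"))[variants + 1L]

  pars <- c(names(truth))
  est <- lapply(vnames, function(v) {
    matrix(NA_real_, runs, length(pars), dimnames = list(NULL, pars))
  })
  names(est) <- vnames
  mse <- se <- rc <- nobs <- conv <-
    lapply(vnames, function(v) rep(NA_real_, runs))
  names(mse) <- names(se) <- names(rc) <- names(nobs) <- names(conv) <- vnames

  for (r in seq_len(runs)) {
    t0 <- proc.time()[3]
    sim <- simulate_run(struct, vc, mode = mode, seed = seeds[r + 1L])
    d0 <- sim$data
    if (scenario == "single-mean") d0 <- dedup_checks(d0)
    for (j in seq_along(variants)) {
      k <- variants[j]; v <- vnames[j]
      d <- if (k == 0) d0 else drop_short_tested(d0, k)
      fit <- reml_fit(d, spec, start = if (start_at_truth) vc else NULL)
      est[[v]][r, ] <- c(fit$vc[setdiff(names(truth), c("beta", "gamma"))],
                         trend_slopes(fit))
      m <- mse_H(fit, sim$truth)
      mse[[v]][r] <- m$mse; se[[v]][r] <- m$se
      rc[[v]][r] <- rank_corr_H(fit, sim$truth)
      nobs[[v]][r] <- nrow(d)
      conv[[v]][r] <- as.numeric(!fit$convergence$converged)
    }
    if (verbose) {
      message(sprintf("run %d/%d done in %.1fs", r, runs,
                      proc.time()[3] - t0))
    }
  }

  summaries <- lapply(vnames, function(v) {
    list(estimates = summarize_runs(est[[v]], truth),
         mse = pooled_mse(mse[[v]], se[[v]]),
         rank_corr = mean(rc[[v]]),
         mean_obs = mean(nobs[[v]]),
         nonconverged = sum(conv[[v]] != 0))
  })
  names(summaries) <- vnames

  structure(list(
    scenario = scenario, runs = runs, seed = seed, params = params,
    vc = vc, truth = truth, variants = vnames, estimates = est,
    mse = mse, mse_se = se, rank_corr = rc, n_obs = nobs,
    convergence = conv, summaries = summaries, structure = struct
  ), class = "vcu_experiment")
}

# generating values on the scale of the reduced analysis model: the
# three-way interaction is part of the residual there
experiment_truth <- function(vc) {
  s <- vc$sigma2
  c(year = unname(s["year"]), location = unname(s["location"]),
    year_location = unname(s["year_location"]), trial = unname(s["trial"]),
    genotype = unname(s["genotype"]),
    genotype_location = unname(s["genotype_location"]),
    genotype_year = unname(s["genotype_year"]),
    residual = unname(s["genotype_year_location"] + s["residual"]),
    beta = vc$beta, gamma = vc$gamma)
}

derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

#' @export
print.vcu_experiment <- function(x, ...) {
  cat(sprintf("Simulation experiment '%s': %d runs, scale %.2f\n",
              x$scenario, x$runs, x$params$scale))
  for (v in x$variants) {
    s <- x$summaries[[v]]
    sl <- s$estimates[s$estimates$parameter %in% c("beta", "gamma"), ]
    cat(sprintf(
      "  %-4s mean obs %.0f | beta %+.3f (%+.3f; %+.3f) | gamma %+.3f | MSE %.2f | rank cor %.3f\n",
      v, s$mean_obs, sl$mean[1], sl$lower[1], sl$upper[1], sl$mean[2],
      s$mse$estimate, s$rank_corr))
  }
  invisible(x)
}

#' Deterministic toy instances for tests and examples
#'
#' `"tiny"` is a single-cycle, three-year skeleton with a handful of cells,
#' small enough to verify against dense hand computations; `"small"` is a
#' four-cycle structure of around a thousand cells that exercises the full
#' pipeline in seconds.
#'
#' @param size `"tiny"` or `"small"`.
#' @return List with `params`, `structure`, the generating `vc`, and a
#'   BLUP-selected `simulation` ([simulate_run()]) carrying data and truth.
#' @export
make_fixture <- function(size = c("tiny", "small")) {
  size <- match.arg(size)
  params <- if (size == "tiny") {
    vcu_structure_params(n_years = 3, n_locations = 4,
                         entries_per_cycle = 4,
                         cull_frac_y1 = 0.5, cull_frac_y2 = 0.25,
                         locs_y1 = 2, locs_y2 = 2, locs_y3 = 2,
                         overlap_y1y2 = 1, overlap_y1y3 = 0,
                         overlap_y2y3 = 1, n_checks = 2,
                         check_span_years = 3, seed = 4242L)
  } else {
    vcu_structure_params(n_years = 6, n_locations = 16,
                         entries_min = 14, entries_max = 20,
                         locs_y1 = 5, locs_y2 = 5, locs_y3 = 8,
                         overlap_y1y2 = 1, overlap_y1y3 = 0,
                         overlap_y2y3 = 2, n_checks = 5,
                         check_span_years = 3, seed = 2424L)
  }
  struct <- build_structure(params)
  vc <- bsa_variance_components()
  sim <- simulate_run(struct, vc, mode = "blup",
                      seed = if (size == "tiny") 11L else 22L)
  list(params = params, structure = struct, vc = vc, simulation = sim)
}
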