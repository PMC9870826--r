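#' Mean squared error of genotype deviation BLUPs
#'
#' Compares the predicted genotype deviations of a fit with the values
#' realized in the simulation, over the genotypes (checks included) tested
#' in at least `min_years` distinct years in the analysed dataset.
#'
#' @param fit a [reml_fit()] result.
#' @param truth the `truth` element of a [simulate_run()] result (or any
#'   list with `effects$genotype`).
#' @param min_years eligibility threshold on distinct testing years.
#' @return List with `mse`, its standard error `se` (standard deviation of
#'   the squared errors over eligible genotypes divided by \eqn{\sqrt{n}}),
#'   and the number of eligible genotypes `n`.
#' @export
mse_H <- function(fit, truth, min_years = 3) {
  g <- eligible_genotypes(fit, min_years)
  if (!length(g)) stop_config("no genotypes tested in >= ", min_years,
                              " years")
  err2 <- (blup_H(fit)[g] - truth$effects$genotype[g])^2
  list(mse = mean(err2), se = stats::sd(err2) / sqrt(length(err2)),
       n = length(err2))
}

eligible_genotypes <- function(fit, min_years = 3) {
  gi <- fit$geno_info
  gi$genotype[gi$n_years >= min_years]
}

#' Spearman rank correlation of predicted and realized genotype deviations
#'
#' @inheritParams mse_H
#' @return The rank correlation over eligible genotypes.
#' @export
rank_corr_H <- function(fit, truth, min_years = 3) {
  g <- eligible_genotypes(fit, min_years)
  stats::cor(blup_H(fit)[g], truth$effects$genotype[g], method = "spearman")
}

#' Fixed-effect meta-analytic pooling of per-run MSE values
#'
#' Pools per-run mean squared errors with inverse-squared-standard-error
#' weights \eqn{w_r = 1/\mathrm{SE}_r^2}; the pooled standard error is
#' \eqn{1/\sqrt{\sum_r w_r}} and the interval is normal-approximation 95\%.
#'
#' @param mse numeric vector of per-run MSE values.
#' @param se their standard errors; non-positive values are floored at a
#'   small constant so that a degenerate run cannot dominate the pool.
#' @return List with `estimate`, `lower`, `upper`, `se`.
#' @export
pooled_mse <- function(mse, se) {
  stopifnot(length(mse) == length(se), length(mse) >= 2)
  w <- 1 / pmax(se, 1e-8)^2
  est <- sum(w * mse) / sum(w)
  pse <- 1 / sqrt(sum(w))
  list(estimate = est, lower = est - 1.96 * pse, upper = est + 1.96 * pse,
       se = pse)
}

#' Across-run summary of variance components and trend slopes
#'
#' Averages per-run parameter estimates and attaches normal-approximation
#' 95\% confidence intervals (mean plus/minus 1.96 standard errors of the
#' mean), the format in which simulation results of this kind are usually
#' tabulated.
#'
#' @param estimates matrix or data frame of per-run estimates, one row per
#'   run, one column per parameter (variance components and slopes).
#' @param truth optional named vector of generating values to tabulate
#'   alongside.
#' @return A data frame of class `vcu_run_summary` with columns
#'   `parameter`, `truth`, `mean`, `lower`, `upper`, `n_runs`.
#' @export
summarize_runs <- function(estimates, truth = NULL) {
  estimates <- as.matrix(estimates)
  if (nrow(estimates) < 2) stop_config("need at least 2 runs for a CI")
  m <- colMeans(estimates)
  half <- 1.96 * apply(estimates, 2, stats::sd) / sqrt(nrow(estimates))
  out <- data.frame(
    parameter = colnames(estimates),
    truth = if (is.null(truth)) NA_real_ else
      unname(truth[colnames(estimates)]),
    mean = unname(m), lower = unname(m - half), upper = unname(m + half),
    n_runs = nrow(estimates), row.names = NULL
  )
  class(out) <- c("vcu_run_summary", "data.frame")
  out
}

#' @export
print.vcu_run_summary <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  for (cc in c("truth", "mean", "lower", "upper")) {
    y[[cc]] <- signif(y[[cc]], digits)
  }
  print(y, row.names = FALSE)
  invisible(x)
}
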