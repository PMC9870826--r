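#' Variance components and trend slopes of the trend-decomposition model
#'
#' Container for the nine variance components of the crossed mixed model for
#' multi-environment variety trial means,
#' \deqn{\bar y_{ijkl} = \mu + \gamma t_k + Z_k + L_j + \beta r_i + H_i +
#'   (LY)_{jk} + (LYT)_{jkl} + (GL)_{ij} + (GY)_{ik} + (GLY)_{ijk} + e_{ijkl},}
#' together with the two fixed trend slopes.  \eqn{t_k} is the calendar year
#' of testing, \eqn{r_i} the year a genotype was first tested; \eqn{\beta}
#' is the genetic and \eqn{\gamma} the non-genetic trend.  All random effects
#' are independent zero-mean normal with homogeneous variance per factor.
#'
#' @param year,location,year_location,trial,genotype,genotype_year,
#'   genotype_location,genotype_year_location,residual variances in
#'   dt^2 ha^-2 (must be non-negative).
#' @param beta genetic trend slope, dt ha^-1 year^-1.
#' @param gamma non-genetic trend slope, dt ha^-1 year^-1.
#' @param mu intercept (overall mean yield, dt ha^-1).
#' @return An object of class `vcu_vc`: a list with element `sigma2`
#'   (named numeric vector of the nine variances) and elements `beta`,
#'   `gamma`, `mu`.
#' @seealso [bsa_variance_components()] for the default parameter set
#'   estimated from the German winter wheat registration series.
#' @export
variance_components <- function(year = 0, location = 0, year_location = 0,
                                trial = 0, genotype = 0, genotype_year = 0,
                                genotype_location = 0,
                                genotype_year_location = 0, residual = 0,
                                beta = 0, gamma = 0, mu = 80) {
  sigma2 <- c(
    year = year, location = location, year_location = year_location,
    trial = trial, genotype = genotype, genotype_year = genotype_year,
    genotype_location = genotype_location,
    genotype_year_location = genotype_year_location, residual = residual
  )
  if (any(!is.finite(sigma2)) || any(sigma2 < 0)) {
    stop_config("all variance components must be finite and >= 0")
  }
  structure(list(sigma2 = sigma2, beta = beta, gamma = gamma, mu = mu),
            class = "vcu_vc")
}

#' Variance components estimated from the German winter wheat VCU series
#'
#' The nine variance components (dt^2 ha^-2) estimated by REML from the
#' 1983--2016 Bundessortenamt winter wheat registration series and used as
#' the generating values of all simulation scenarios.  Trend slopes default
#' to zero: the simulations generate trend-free data so that any non-zero
#' estimated trend is pure bias.
#'
#' @param inflate_genotype_year if `TRUE`, the genotype-by-year variance is
#'   raised from 3.16 to 55.75 (the scenario probing how the bias scales
#'   with genotype-by-year variance); all other components are unchanged.
#' @param mu intercept, dt ha^-1.  Cancels from every bias metric.
#' @return A `vcu_vc` object, see [variance_components()].
#' @export
bsa_variance_components <- function(inflate_genotype_year = FALSE, mu = 80) {
  variance_components(
    year = 25.13, location = 53.15, year_location = 74.14, trial = 8.83,
    genotype = 13.27,
    genotype_year = if (inflate_genotype_year) 55.75 else 3.16,
    genotype_location = 2.25, genotype_year_location = 9.62, residual = 9.36,
    beta = 0, gamma = 0, mu = mu
  )
}

#' @export
print.vcu_vc <- function(x, ...) {
  cat("Variance components (dt^2/ha^2):\n")
  print(round(x$sigma2, 3))
  cat(sprintf("slopes: beta (genetic) = %g, gamma (non-genetic) = %g; mu = %g\n",
              x$beta, x$gamma, x$mu))
  invisible(x)
}

# condition helper used across the package for invalid configurations
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("vcu_config_error", "error")))
}
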