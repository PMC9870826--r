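#' @title Within-cycle informative selection
#' @description
#' The culling decisions applied after the first and second year of each
#' testing cycle.  Candidates are ranked by the best linear unbiased
#' prediction (BLUP) of their genotype effect from a mixed model fitted to
#' the cycle's own data (checks included), using the generating variance
#' components confounded to the factors identifiable within a cycle.
#' Selecting on the analysed trait makes the later drop-out informative
#' (missing not at random); [select_random()] provides the
#' missing-completely-at-random benchmark.
#' @name selection
NULL

# variances of the single-year model: G takes up genotype-by-year, L takes
# up year-by-location and trial, the residual takes up genotype-by-location,
# the three-way interaction and plot error
confound_vc_year1 <- function(vc) {
  s <- vc$sigma2
  list(vars = c(location = unname(s["location"] + s["year_location"] + s["trial"]),
                genotype = unname(s["genotype"] + s["genotype_year"])),
       ve = unname(s["genotype_location"] + s["genotype_year_location"] +
                   s["residual"]))
}

# variances of the two-year model: year-by-location absorbs the trial
# effect (one trial per year-location within a cycle), the residual is the
# confounded three-way interaction and plot error
confound_vc_year2 <- function(vc) {
  s <- vc$sigma2
  list(vars = c(year = unname(s["year"]),
                location = unname(s["location"]),
                genotype = unname(s["genotype"]),
                year_location = unname(s["year_location"] + s["trial"]),
                genotype_location = unname(s["genotype_location"]),
                genotype_year = unname(s["genotype_year"])),
       ve = unname(s["genotype_year_location"] + s["residual"]))
}

# Henderson mixed-model equations with known variances: returns the BLUPs
# of each random factor.  Sparse; a single solve, no iteration.
solve_mme_known <- function(y, factors, vars, ve) {
  n <- length(y)
  Zs <- lapply(factors, indicator_matrix)
  W <- do.call(cbind, c(list(Matrix::Matrix(1, n, 1, sparse = TRUE)), Zs))
  q <- vapply(Zs, ncol, integer(1))
  dpen <- c(0, rep(ve / vars, times = q))
  M <- Matrix::forceSymmetric(Matrix::crossprod(W)) +
    Matrix::Diagonal(x = dpen)
  sol <- Matrix::solve(M, Matrix::crossprod(W, y))
  sol <- as.numeric(sol)
  out <- list(mu = sol[1])
  at <- 1L
  for (i in seq_along(Zs)) {
    vals <- sol[at + seq_len(q[i])]
    names(vals) <- colnames(Zs[[i]])
    out[[names(factors)[i]]] <- vals
    at <- at + q[i]
  }
  out
}

rank_candidates <- function(blups, candidates, n_keep) {
  if (n_keep > length(candidates)) {
    stop("n_keep (", n_keep, ") exceeds the number of candidates (",
         length(candidates), ")", call. = FALSE)
  }
  g <- blups[candidates]
  # ties (measure zero) broken deterministically by entry id
  candidates[order(-g, candidates)][seq_len(n_keep)]
}

#' Select year-2 survivors from a cycle's first-year data
#'
#' Fits the single-year model \eqn{\bar y_{ij} = \mu + L_j + G_i + e_{ij}}
#' with random location and genotype effects (all cells of the cycle's
#' year-1 trials, checks included), where each effect is the within-cycle
#' confounded version of the full model's factors, and returns the
#' `n_keep` candidates with the largest genotype BLUPs.
#'
#' @param data year-1 cells of one cycle (columns `genotype`, `role`,
#'   `location`, `y`).
#' @param n_keep number of candidates to keep.
#' @param vc generating [variance_components()]; confounded internally to
#'   the three variances of the single-year model.
#' @return Character vector of selected entry ids, in rank order.
#' @export
select_year1 <- function(data, n_keep, vc) {
  cvc <- confound_vc_year1(vc)
  fit <- solve_mme_known(data$y,
                         list(location = factor(data$location),
                              genotype = factor(data$genotype)),
                         cvc$vars, cvc$ve)
  rank_candidates(fit$genotype,
                  sort(unique(data$genotype[data$role == "candidate"])),
                  n_keep)
}

#' Select year-3 survivors from a cycle's first two years of data
#'
#' Fits the two-year model with random year, location, genotype,
#' year-by-location, genotype-by-location and genotype-by-year effects
#' (year-by-location confounded with trial, the residual confounded with
#' the three-way interaction), and returns the `n_keep` candidates with the
#' largest genotype BLUPs.
#'
#' @param data cells of series-years 1 and 2 of one cycle: the year-2
#'   survivors' candidate data plus the checks of both series.
#' @inheritParams select_year1
#' @return Character vector of selected entry ids, in rank order.
#' @export
select_year2 <- function(data, n_keep, vc) {
  cvc <- confound_vc_year2(vc)
  fit <- solve_mme_known(
    data$y,
    list(year = factor(data$year),
         location = factor(data$location),
         genotype = factor(data$genotype),
         year_location = factor(ekey(data$year, data$location)),
         genotype_location = factor(ekey(data$genotype, data$location)),
         genotype_year = factor(ekey(data$genotype, data$year))),
    cvc$vars, cvc$ve)
  rank_candidates(fit$genotype,
                  sort(unique(data$genotype[data$role == "candidate"])),
                  n_keep)
}

#' Random (uninformative) selection
#'
#' Uniform sampling of survivors without replacement; the benchmark whose
#' drop-out is missing completely at random.
#'
#' @param entries candidate entry ids.
#' @param n_keep number to keep.
#' @param seed optional seed; by default the current RNG stream is used.
#' @return Character vector of selected ids.
#' @export
select_random <- function(entries, n_keep, seed = NULL) {
  if (n_keep > length(entries)) {
    stop("n_keep (", n_keep, ") exceeds the number of candidates (",
         length(entries), ")", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sort(sample(entries, n_keep))
}
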