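#' Drop candidates tested in few years
#'
#' Removes all observations of candidate genotypes whose number of distinct
#' testing years is at most `max_years`.  Genotypes with any check
#' observations are never removed (the check panel is what connects the
#' series).  Applied after phenotype-based selection this reduction is
#' informative (missing not at random), because staying beyond year 1 or 2
#' depends on the analysed trait; after random selection it is MCAR.
#'
#' @param data a simulated (or assembled) dataset.
#' @param max_years drop candidates tested in up to this many distinct
#'   years (1 or 2 for the standard reduced variants).
#' @return The reduced dataset.
#' @export
drop_short_tested <- function(data, max_years) {
  stopifnot(max_years >= 0)
  years <- tapply(data$year, data$genotype, function(x) length(unique(x)))
  is_check_geno <- unique(data$genotype[data$role == "check"])
  short <- names(years)[years <= max_years]
  short <- setdiff(short, is_check_geno)
  out <- data[!(data$genotype %in% short), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Randomly de-duplicate check observations
#'
#' Only check varieties can occur more than once within a year-by-location
#' combination (once per parallel series).  This reduction keeps exactly one
#' observation per (genotype, year, location) triple, chosen uniformly at
#' random, yielding the single-mean dataset variant whose analysis model
#' coincides with the generating model.  The step is completely at random
#' and therefore does not alter the missingness pattern.
#'
#' @param data a simulated dataset.
#' @param seed optional seed; by default the current RNG stream is used.
#' @return The de-duplicated dataset (one row per genotype-year-location).
#' @export
dedup_checks <- function(data, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  key <- ekey(data$genotype, data$year, data$location)
  ord <- sample.int(nrow(data))  # random tie-break, then keep first per key
  keep <- ord[!duplicated(key[ord])]
  out <- data[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
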