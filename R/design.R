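#' Specify a trend-decomposition mixed model
#'
#' A model spec names the fixed covariates (subset of `t`, the calendar year
#' of testing, and `r`, the year of first testing -- both numeric and
#' uncentered) and the random factors, each given as a grouping key over
#' dataset columns, e.g. `"year"`, `"genotype:location"`.  The residual is
#' always present.
#'
#' @param fixed character vector, subset of `c("t", "r")`.
#' @param random character vector of grouping keys; components of a key are
#'   separated by `:` and must name dataset columns.
#' @return A list of class `vcu_model_spec`.
#' @seealso [trend_model_spec()] for the standard analysis models.
#' @export
model_spec <- function(fixed = c("t", "r"),
                       random = c("year", "location", "genotype",
                                  "year:location", "trial",
                                  "genotype:location", "genotype:year")) {
  if (!all(fixed %in% c("t", "r"))) {
    stop_config("fixed covariates must be a subset of c('t', 'r')")
  }
  if (anyDuplicated(random)) stop_config("duplicate random factors")
  structure(list(fixed = fixed, random = random), class = "vcu_model_spec")
}

#' The standard analysis model for simulated registration series
#'
#' With `separate_three_way = FALSE` (the default) this is the reduced
#' analysis model: intercept, the two trend regressions, and random year,
#' location, genotype, year-by-location, trial, genotype-by-location and
#' genotype-by-year effects, with the genotype-by-year-by-location
#' interaction confounded with the residual.  With
#' `separate_three_way = TRUE` the three-way interaction is a separate
#' factor; it is identifiable only through check varieties observed more
#' than once within a year-by-location combination, and is collapsed back
#' into the residual automatically when a dataset carries no such
#' duplicates.
#'
#' @param separate_three_way separate the genotype-by-year-by-location
#'   effect from the residual.
#' @return A `vcu_model_spec`.
#' @export
trend_model_spec <- function(separate_three_way = FALSE) {
  rand <- c("year", "location", "genotype", "year:location", "trial",
            "genotype:location", "genotype:year")
  if (separate_three_way) rand <- c(rand, "genotype:year:location")
  model_spec(fixed = c("t", "r"), random = rand)
}

# canonical variance-component name for a grouping key
term_vc_name <- function(term) {
  map <- c("year" = "year", "location" = "location", "genotype" = "genotype",
           "year:location" = "year_location", "trial" = "trial",
           "genotype:location" = "genotype_location",
           "genotype:year" = "genotype_year",
           "genotype:year:location" = "genotype_year_location")
  ifelse(term %in% names(map), map[term], gsub(":", "_", term))
}

term_key <- function(data, term) {
  cols <- strsplit(term, ":", fixed = TRUE)[[1]]
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    stop_config("grouping key '", term, "' needs missing column(s): ",
                paste(miss, collapse = ", "))
  }
  if (length(cols) == 1L) as.character(data[[cols]])
  else do.call(ekey, data[cols])
}

indicator_matrix <- function(f) {
  f <- as.factor(f)
  Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                       dims = c(length(f), nlevels(f)),
                       dimnames = list(NULL, levels(f)))
}

# drop the separate three-way factor when no genotype carries duplicate
# observations within a year-by-location combination
validate_model_spec <- function(spec, data) {
  tw <- "genotype:year:location"
  if (tw %in% spec$random && !anyDuplicated(term_key(data, tw))) {
    message("no duplicate genotype-by-year-by-location observations: ",
            "collapsing the three-way interaction into the residual")
    spec$random <- setdiff(spec$random, tw)
  }
  spec
}

#' Build the sparse model components for a dataset and model spec
#'
#' @param data dataset with columns `y`, `year`, `location`, `genotype`,
#'   `trial`, `first_year` (as required by the spec's keys).
#' @param spec a [model_spec()].
#' @return List with the response `y`, the dense fixed-effect design `X`
#'   (intercept plus requested covariates), one sparse indicator matrix per
#'   random factor in `Z`, the level counts `q` and the factor `terms`.
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(spec, "vcu_model_spec"))
  if (!"y" %in% names(data)) stop_config("dataset has no response column 'y'")
  y <- data$y
  X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  if ("t" %in% spec$fixed) {
    X <- cbind(X, t = as.numeric(data$year))
  }
  if ("r" %in% spec$fixed) {
    X <- cbind(X, r = as.numeric(data$first_year))
  }
  Z <- lapply(spec$random, function(term) {
    indicator_matrix(term_key(data, term))
  })
  names(Z) <- spec$random
  list(y = y, X = X, Z = Z, q = vapply(Z, ncol, integer(1)),
       terms = spec$random)
}
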