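#' @title Realized random-effect store
#' @description
#' An effect set holds one realized value per level of each random factor of
#' the simulation model.  Levels are created lazily: the first time a level
#' key is requested its effect is drawn from a zero-mean normal with the
#' factor's variance, after which the value is fixed for the rest of the
#' simulation run.  Year, location, year-by-location and trial effects are
#' requested once up front by [simulate_run()], so they are shared by all
#' cycles and all checks of a run; genotype-level effects are drawn as each
#' cycle is simulated.
#' @param vc a [variance_components()] object.
#' @return An environment of class `vcu_effects` with one named numeric
#'   vector per factor.
#' @keywords internal
new_effect_set <- function(vc) {
  e <- new.env(parent = emptyenv())
  e$sd <- sqrt(vc$sigma2)
  for (f in names(vc$sigma2)) assign(f, numeric(0), envir = e)
  class(e) <- "vcu_effects"
  e
}

# look up effects for a vector of level keys, drawing missing levels in
# order of first appearance
effect_get <- function(effects, factor, keys) {
  vals <- get(factor, envir = effects)
  new <- setdiff(unique(keys), names(vals))
  if (length(new)) {
    drawn <- stats::rnorm(length(new), 0, effects$sd[[factor]])
    vals <- c(vals, stats::setNames(drawn, new))
    assign(factor, vals, envir = effects)
  }
  unname(vals[keys])
}

effect_has <- function(effects, factor, key) {
  key %in% names(get(factor, envir = effects))
}

# composite level keys; "|" never occurs in ids
ekey <- function(...) paste(..., sep = "|")

# plain-list snapshot of all realized effects (the "truth" attached to a
# simulated dataset)
as_effect_list <- function(effects) {
  out <- lapply(names(effects$sd), function(f) get(f, envir = effects))
  names(out) <- names(effects$sd)
  out
}

#' Transfer genotype-level effects from a candidate to a check variety
#'
#' Successful candidates that are promoted to check varieties keep their
#' genotype effect and their genotype-by-location effects: the variety in
#' later check years is the same genotype that was tested as a candidate.
#' This helper copies those effect values from the candidate's key to the
#' check's key in an effect store.  Year-linked effects (genotype-by-year,
#' genotype-by-year-by-location, plot error) are never copied; they are
#' drawn fresh for the check's years.
#'
#' [simulate_run()] represents promoted checks by re-using the candidate's
#' genotype id directly, which makes the transfer implicit; this explicit
#' copy is provided for workflows that keep separate labels.
#'
#' @param effects a `vcu_effects` store.
#' @param candidate genotype id whose effects are transferred.
#' @param check_id target genotype id (the check's label).
#' @return The effect store, invisibly (modified in place).
#' @export
transfer_check_effects <- function(effects, candidate, check_id) {
  if (effect_has(effects, "genotype", check_id)) {
    stop(errorCondition(
      sprintf("check '%s' already carries a genotype effect", check_id),
      class = c("vcu_consistency_error", "error")))
  }
  h <- effect_get(effects, "genotype", candidate)
  vals <- get("genotype", envir = effects)
  vals[check_id] <- h
  assign("genotype", vals, envir = effects)

  gl <- get("genotype_location", envir = effects)
  pre <- paste0(candidate, "|")
  src <- names(gl)[startsWith(names(gl), pre)]
  if (length(src)) {
    tgt <- sub(pre, paste0(check_id, "|"), src, fixed = TRUE)
    keep <- !(tgt %in% names(gl))
    if (any(keep)) {
      gl[tgt[keep]] <- gl[src[keep]]
      assign("genotype_location", gl, envir = effects)
    }
  }
  invisible(effects)
}
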