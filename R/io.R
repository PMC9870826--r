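#' Read and write pipeline artifacts as delimited text
#'
#' Datasets, trial structures and fit results are exchanged as plain CSV
#' tables; a structure additionally carries a JSON sidecar
#' (`<path>.meta.json`) with its generating parameters and registries so
#' that a round trip reproduces the object exactly.
#'
#' @param data,structure,fit object to write.
#' @param path file path (CSV).
#' @name vcu-io
NULL

#' @rdname vcu-io
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname vcu-io
#' @export
read_dataset <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname vcu-io
#' @export
write_structure <- function(structure, path) {
  utils::write.csv(structure$cells, path, row.names = FALSE, quote = FALSE)
  meta <- list(
    params = unclass(structure$params),
    cycles = structure$cycles,
    cycle_locs = structure$cycle_locs,
    checks = structure$checks
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname vcu-io
#' @export
read_structure <- function(path) {
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  cells$check_id[cells$check_id == ""] <- NA_character_
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  params <- meta$params
  params$entries_per_cycle <- params$entries_per_cycle %||% NULL
  class(params) <- "vcu_structure_params"
  structure(list(params = params, cycles = meta$cycles,
                 cycle_locs = meta$cycle_locs, checks = meta$checks,
                 cells = cells),
            class = "vcu_structure")
}

#' @rdname vcu-io
#' @export
write_fit <- function(fit, path) {
  vc <- data.frame(component = names(fit$vc), estimate = unname(fit$vc))
  utils::write.csv(vc, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(fit$fixed, sub("\\.csv$", ".fixed.csv", path),
                   row.names = FALSE, quote = FALSE)
  blup <- data.frame(genotype = names(blup_H(fit)),
                     blup = unname(blup_H(fit)))
  utils::write.csv(blup, sub("\\.csv$", ".blup.csv", path),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(loglik = fit$loglik, n = fit$n, convergence = fit$convergence),
    paste0(path, ".meta.json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}
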