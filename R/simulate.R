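#' Compute phenotypic means for a set of observation cells
#'
#' Sums the intercept, the two trend terms and all realized random effects
#' for each row, drawing effects that have not been realized yet.  Each row
#' must carry `genotype`, `year`, `location`, `trial` and `first_year`.
#'
#' @param rows data frame of cells.
#' @param effects a `vcu_effects` store.
#' @param vc the generating [variance_components()].
#' @param keep_components if `TRUE` the individual effect columns are
#'   returned alongside `y` (used to verify exact reconstruction).
#' @return `rows` with a column `y` (and component columns if requested).
#' @keywords internal
resolve_y <- function(rows, effects, vc, keep_components = FALSE) {
  comp <- data.frame(
    mu = rep(vc$mu, nrow(rows)),
    trend_t = vc$gamma * rows$year,
    trend_r = vc$beta * rows$first_year,
    year = effect_get(effects, "year", as.character(rows$year)),
    location = effect_get(effects, "location", as.character(rows$location)),
    genotype = effect_get(effects, "genotype", rows$genotype),
    year_location = effect_get(effects, "year_location",
                               ekey(rows$year, rows$location)),
    trial = effect_get(effects, "trial", rows$trial),
    genotype_location = effect_get(effects, "genotype_location",
                                   ekey(rows$genotype, rows$location)),
    genotype_year = effect_get(effects, "genotype_year",
                               ekey(rows$genotype, rows$year)),
    genotype_year_location = effect_get(effects, "genotype_year_location",
                                        ekey(rows$genotype, rows$year,
                                             rows$location)),
    residual = effect_get(effects, "residual", ekey(rows$genotype, rows$trial))
  )
  rows$y <- rowSums(comp)
  if (keep_components) {
    names(comp) <- paste0("eff_", names(comp))
    rows <- cbind(rows, comp)
  }
  rows
}

#' Simulate the complete three-year data of one cycle
#'
#' Generates phenotypic means for *every* entry of a cycle in all three
#' series-years at the cycle's location sets -- i.e. the counterfactual
#' complete data before any culling.  Genotype-level effects (genotype,
#' genotype-by-year, genotype-by-location, three-way, error) are drawn
#' fresh for the cycle's entries; year, location, year-by-location and
#' trial effects are taken from the shared per-run store.
#'
#' @param structure a [build_structure()] skeleton.
#' @param cycle cycle id (integer).
#' @param vc generating [variance_components()].
#' @param effects shared `vcu_effects` store of the run.
#' @return Data frame of candidate cells (all entries, all three years)
#'   with simulated `y`.
#' @export
simulate_cycle_full <- function(structure, cycle, vc, effects) {
  cyc <- structure$cycles
  if (!cycle %in% cyc$cycle) {
    stop_config("unknown cycle id: ", cycle)
  }
  n <- cyc$n_entries[cyc$cycle == cycle]
  ids <- entry_ids(cycle, n)
  locs <- structure$cycle_locs[structure$cycle_locs$cycle == cycle, ]
  locs <- locs[order(locs$series_year, locs$location), ]
  rows <- data.frame(
    genotype = rep(ids, each = nrow(locs)),
    role = "candidate",
    cycle = cycle,
    series_year = rep(locs$series_year, n),
    year = rep(locs$year, n),
    first_year = cyc$start_year[cyc$cycle == cycle],
    location = rep(locs$location, n),
    trial = trial_ids(rep(locs$year, n), rep(locs$location, n), cycle),
    stringsAsFactors = FALSE
  )
  rows <- rows[order(rows$series_year, rows$genotype, rows$location), ]
  rownames(rows) <- NULL
  resolve_y(rows, effects, vc)
}

# simulated data for the check cells of one cycle's series (used in the
# within-cycle selection fits); genotype identities come from the current
# (partial) check assignment
check_data_for <- function(structure, cycle, series, effects, vc,
                           assignment) {
  cells <- structure$cells
  sub <- cells[cells$role == "check" & cells$cycle == cycle &
               cells$series_year %in% series, , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  sub$genotype <- assignment$genotype[sub$check_id]
  sub$first_year <- assignment$first_year[sub$check_id]
  sub <- sub[order(sub$series_year, sub$check_id, sub$location), ]
  sub <- sub[c("genotype", "role", "cycle", "series_year", "year",
               "first_year", "location", "trial")]
  rownames(sub) <- NULL
  resolve_y(sub, effects, vc)
}

#' Fill a trial skeleton with simulated data given a selection outcome
#'
#' Emits exactly one row per structure cell.  Survivor slots of years 2 and
#' 3 carry the selected entries (the equivalent of exchanging genotype and
#' genotype-by-location labels after each selection step while keeping the
#' observed layout fixed), and former-candidate checks take over the
#' identity of a selected year-3 survivor of their source cycle, so their
#' genotype and genotype-by-location effects continue seamlessly.
#'
#' @param structure a [build_structure()] skeleton.
#' @param vc generating [variance_components()].
#' @param effects the run's `vcu_effects` store.
#' @param selection per-cycle list with elements `kept2`, `kept3` (entry ids
#'   in rank order), as produced by the selection step of [simulate_run()].
#' @param check_assignment optional mapping of checks to genotype ids; when
#'   missing it is derived from `selection`.
#' @param keep_components attach per-row effect columns.
#' @return Data frame with one row per cell: `genotype`, `role`, `cycle`,
#'   `series_year`, `year`, `first_year`, `location`, `trial`, `y`.
#' @export
assemble_dataset <- function(structure, vc, effects, selection,
                             check_assignment = NULL,
                             keep_components = FALSE) {
  cyc <- structure$cycles
  for (cc in cyc$cycle) {
    s <- selection[[cc]]
    if (is.null(s) || length(s$kept2) != cyc$n_keep2[cc] ||
        length(s$kept3) != cyc$n_keep3[cc]) {
      stop("selection outcome does not cover the survivor slots of cycle ",
           cc, call. = FALSE)
    }
  }
  res <- resolve_cells(structure, selection, check_assignment)
  rows <- res$cells[c("genotype", "role", "cycle", "series_year", "year",
                      "first_year", "location", "trial")]
  resolve_y(rows, effects, vc, keep_components = keep_components)
}

#' Simulate one complete run: draw effects, select, assemble
#'
#' Runs the full generative protocol for one dataset: shared year, location,
#' year-by-location and trial effects are drawn once; each cycle's complete
#' three-year data are simulated; survivors into year 2 are chosen from the
#' year-1 data and survivors into year 3 from the years-1--2 data of the
#' year-2 survivors (checks included in both fits); finally the skeleton is
#' filled with the selected identities.  With `mode = "blup"` the selection
#' ranks candidates by the BLUP of their genotype effect (informative,
#' MNAR-generating); with `mode = "random"` survivors are sampled uniformly
#' (the MCAR benchmark).
#'
#' @param structure a [build_structure()] skeleton.
#' @param vc generating [variance_components()]; zero trend slopes by
#'   default, so any non-zero trend estimate downstream is bias.
#' @param mode `"blup"` or `"random"`.
#' @param seed integer seed; one seed fully reproduces the run.
#' @param keep_components attach per-row effect columns to the dataset.
#' @return An object of class `vcu_simulation`: list with `data` (the
#'   assembled dataset), `truth` (realized effects, generating variance
#'   components, the selection outcome and the check-to-genotype map),
#'   `mode` and `seed`.
#' @export
simulate_run <- function(structure, vc = bsa_variance_components(),
                         mode = c("blup", "random"), seed = 1L,
                         keep_components = FALSE) {
  mode <- match.arg(mode)
  set.seed(seed)
  eff <- new_effect_set(vc)
  cells <- structure$cells

  # shared, once-per-run effects, drawn in a fixed order
  effect_get(eff, "year", as.character(seq_len(structure$params$n_years)))
  effect_get(eff, "location",
             as.character(seq_len(structure$params$n_locations)))
  yl <- unique(ekey(cells$year, cells$location))
  effect_get(eff, "year_location", sort(yl))
  effect_get(eff, "trial", sort(unique(cells$trial)))

  cyc <- structure$cycles
  checks <- structure$checks[order(structure$checks$start_year,
                                   structure$checks$check_id), ]
  assignment <- list(
    genotype = stats::setNames(checks$check_id, checks$check_id),
    first_year = stats::setNames(checks$start_year, checks$check_id)
  )
  used <- character(0)
  selection <- vector("list", nrow(cyc))

  for (cc in cyc$cycle) {
    full <- simulate_cycle_full(structure, cc, vc, eff)
    entries <- entry_ids(cc, cyc$n_entries[cc])
    if (mode == "blup") {
      d1 <- rbind(full[full$series_year == 1L, , drop = FALSE],
                  check_data_for(structure, cc, 1L, eff, vc, assignment))
      kept2 <- select_year1(d1, cyc$n_keep2[cc], vc)
      d12 <- rbind(
        full[full$series_year <= 2L & full$genotype %in% kept2, ,
             drop = FALSE],
        check_data_for(structure, cc, c(1L, 2L), eff, vc, assignment))
      kept3 <- select_year2(d12, cyc$n_keep3[cc], vc)
    } else {
      kept2 <- select_random(entries, cyc$n_keep2[cc])
      kept3 <- select_random(kept2, cyc$n_keep3[cc])
    }
    selection[[cc]] <- list(kept2 = kept2, kept3 = kept3)

    # promote survivors to checks whose activity descends from this cycle
    for (i in which(checks$source_cycle == cc)) {
      avail <- setdiff(kept3, used)
      if (!length(avail)) next
      assignment$genotype[checks$check_id[i]] <- avail[1]
      assignment$first_year[checks$check_id[i]] <- cyc$start_year[cc]
      used <- c(used, avail[1])
    }
  }

  data <- assemble_dataset(structure, vc, eff, selection, assignment,
                           keep_components = keep_components)
  structure(list(
    data = data,
    truth = list(vc = vc, effects = as_effect_list(eff),
                 selection = selection, check_genotype = assignment),
    mode = mode, seed = seed
  ), class = "vcu_simulation")
}

#' @export
print.vcu_simulation <- function(x, ...) {
  cat(sprintf(
    "Simulated VCU dataset: %d observations, %d genotypes, %s selection\n",
    nrow(x$data), length(unique(x$data$genotype)), x$mode))
  invisible(x)
}
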