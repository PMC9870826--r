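#' Parameters of the VCU trial structure generator
#'
#' Assembles (and validates) the parameter set from which [build_structure()]
#' generates a registration-trial skeleton: overlapping three-year testing
#' cycles, per-series location sets with prescribed expected overlaps,
#' preplanned survivor counts after the year-1 and year-2 cullings, and a
#' staggered panel of long-running check varieties.
#'
#' Defaults at `scale = 1` reproduce the aggregate geometry of the German
#' winter wheat registration series 1983--2016: 34 years, a pool of 120
#' locations, per-cycle entry counts ramping from about 60 to about 120,
#' 51\% / 26\% of entries culled after the first / second year, series tested
#' at about 11, 13 and 24 locations in years 1--3 with expected overlaps of
#' 2, 1 and 8 locations between series-years of a cycle, and 48 checks active
#' for about 7 years each.
#'
#' The `scale` argument shrinks the design proportionally for desk-scale
#' experimentation: counts along the time and genotype axes (years,
#' location pool, entries, checks) scale linearly, while per-series location
#' counts, overlaps and check spans scale with `sqrt(scale)` so that the
#' per-observation information content degrades gracefully.
#'
#' @param scale global size multiplier in (0, 1]; `scale = 0.25` gives a
#'   design of roughly 9 years, 30 locations and 3--4 thousand observations.
#' @param n_years number of calendar years.
#' @param n_locations size of the location pool.
#' @param entries_min,entries_max end points of the linear per-cycle entry
#'   ramp (first to last cycle).
#' @param entries_per_cycle optional explicit schedule of per-cycle entry
#'   counts (overrides the ramp); recycled to the number of cycles.
#' @param cull_frac_y1 fraction of a cycle's entries culled after year 1.
#' @param cull_frac_y2 fraction culled after year 2 (scalar or per-cycle).
#' @param locs_y1,locs_y2,locs_y3 locations per series-year.
#' @param overlap_y1y2,overlap_y1y3,overlap_y2y3 expected number of shared
#'   locations between the series-years of one cycle.
#' @param n_checks number of check varieties.
#' @param check_span_years mean number of active years per check.
#' @param seed RNG seed used when drawing location sets and check spans.
#' @return A validated list of class `vcu_structure_params`.
#' @export
vcu_structure_params <- function(scale = 1,
                                 n_years = NULL, n_locations = NULL,
                                 entries_min = NULL, entries_max = NULL,
                                 entries_per_cycle = NULL,
                                 cull_frac_y1 = 0.51, cull_frac_y2 = 0.26,
                                 locs_y1 = NULL, locs_y2 = NULL,
                                 locs_y3 = NULL,
                                 overlap_y1y2 = NULL, overlap_y1y3 = NULL,
                                 overlap_y2y3 = NULL,
                                 n_checks = NULL, check_span_years = NULL,
                                 seed = 1L) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0 || scale > 1) {
    stop_config("'scale' must be a single number in (0, 1]")
  }
  rnd <- function(x) floor(x + 0.5)  # deterministic half-up rounding
  s <- scale
  p <- list(
    n_years     = n_years     %||% max(3L,  rnd(34 * s)),
    n_locations = n_locations %||% max(4L,  rnd(120 * s)),
    entries_min = entries_min %||% max(4L,  rnd(60 * s)),
    entries_max = entries_max %||% max(4L,  rnd(120 * s)),
    entries_per_cycle = entries_per_cycle,
    cull_frac_y1 = cull_frac_y1,
    cull_frac_y2 = cull_frac_y2,
    locs_y1 = locs_y1 %||% max(2L, rnd(11 * sqrt(s))),
    locs_y2 = locs_y2 %||% max(2L, rnd(13 * sqrt(s))),
    locs_y3 = locs_y3 %||% max(2L, rnd(24 * sqrt(s))),
    overlap_y1y2 = overlap_y1y2 %||% rnd(2 * sqrt(s)),
    overlap_y1y3 = overlap_y1y3 %||% rnd(1 * sqrt(s)),
    overlap_y2y3 = overlap_y2y3 %||% max(1L, rnd(8 * sqrt(s))),
    n_checks = n_checks %||% max(2L, rnd(48 * s)),
    check_span_years = check_span_years %||% max(3L, rnd(7 * sqrt(s))),
    scale = s,
    seed = as.integer(seed)
  )
  validate_structure_params(p)
  class(p) <- "vcu_structure_params"
  p
}

validate_structure_params <- function(p) {
  if (p$n_years < 3) stop_config("'n_years' must be at least 3")
  if (any(p$cull_frac_y1 + p$cull_frac_y2 >= 1)) {
    stop_config("cull_frac_y1 + cull_frac_y2 must be < 1")
  }
  if (any(p$cull_frac_y1 < 0) || any(p$cull_frac_y2 < 0)) {
    stop_config("culling fractions must be >= 0")
  }
  locs <- c(p$locs_y1, p$locs_y2, p$locs_y3)
  if (any(locs > p$n_locations)) {
    stop_config("locations per series-year cannot exceed the location pool")
  }
  o <- c(p$overlap_y1y2, p$overlap_y1y3, p$overlap_y2y3)
  if (any(o < 0)) stop_config("overlaps must be >= 0")
  if (p$overlap_y1y2 + p$overlap_y1y3 > p$locs_y1 ||
      p$overlap_y1y2 + p$overlap_y2y3 > p$locs_y2 ||
      p$overlap_y1y3 + p$overlap_y2y3 > p$locs_y3) {
    stop_config("requested overlaps exceed the per-series location counts")
  }
  if (sum(locs) - sum(o) > p$n_locations) {
    stop_config("location pool too small for the requested per-cycle ",
                "location sets and overlaps")
  }
  entries <- p$entries_per_cycle %||% c(p$entries_min, p$entries_max)
  keep3 <- floor(entries * (1 - p$cull_frac_y1 - max(p$cull_frac_y2)) + 0.5)
  if (any(keep3 < 1)) {
    stop_config("survivor count in year 3 would fall below 1; increase the ",
                "entry counts or reduce the culling fractions")
  }
  invisible(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

entry_ids <- function(cycle, n) sprintf("C%02dE%03d", cycle, seq_len(n))
check_ids <- function(n) sprintf("CHK%02d", seq_len(n))
trial_ids <- function(year, location, cycle) {
  sprintf("Y%02d.L%03d.C%02d", year, location, cycle)
}

#' Generate a VCU-like trial skeleton
#'
#' Builds the observation skeleton of a registration trial series from
#' summary parameters: which genotype slot is observed in which year,
#' location and trial, which slots are candidate slots of which cycle, and
#' which cells belong to check varieties.  No phenotypic data are involved;
#' the skeleton is the fixed layout that [simulate_run()] fills in.
#'
#' A cycle starting in year \eqn{c} is tested in years \eqn{c, c+1, c+2};
#' no cycle starts after year `n_years - 2`, so all cycles complete.  All
#' entries of a cycle are tested in year 1; year-2 and year-3 candidate
#' slots are preplanned survivor slots filled later by a selection outcome.
#' Each (year, location, series) triple is one trial; a year-by-location
#' combination testing several parallel series holds that many trials.
#' Checks appear in every trial of every year in which they are active, and
#' are the only genotypes that can occur more than once within a
#' year-by-location combination.  Checks whose activity starts late enough
#' are flagged as former candidates of the cycle finishing just before their
#' first check year; at assembly time such a check inherits the identity
#' (and hence the genotype and genotype-by-location effects) of a selected
#' year-3 survivor of that cycle.
#'
#' @param params a [vcu_structure_params()] object.
#' @return An object of class `vcu_structure`: a list with data frames
#'   `cells` (one row per observation slot), `cycles` (entry and survivor
#'   counts), `cycle_locs` (per-series location sets), `checks` (activity
#'   window and source cycle) and the generating `params`.
#' @export
build_structure <- function(params) {
  if (!inherits(params, "vcu_structure_params")) {
    params <- do.call(vcu_structure_params, as.list(params))
  }
  set.seed(params$seed)
  n_years <- params$n_years
  n_cycles <- n_years - 2L

  entries <- params$entries_per_cycle
  if (is.null(entries)) {
    entries <- floor(seq(params$entries_min, params$entries_max,
                         length.out = n_cycles) + 0.5)
  } else {
    entries <- rep_len(as.integer(entries), n_cycles)
  }
  cull2 <- rep_len(params$cull_frac_y2, n_cycles)
  n_keep2 <- pmax(1L, as.integer(floor(entries * (1 - params$cull_frac_y1) + 0.5)))
  n_keep3 <- pmax(1L, as.integer(floor(entries * (1 - params$cull_frac_y1 - cull2) + 0.5)))
  n_keep3 <- pmin(n_keep3, n_keep2)
  cycles <- data.frame(cycle = seq_len(n_cycles),
                       start_year = seq_len(n_cycles),
                       n_entries = as.integer(entries),
                       n_keep2 = n_keep2, n_keep3 = n_keep3)

  # per-cycle location sets: draw the pairwise-overlap groups first, then
  # top up each series-year with locations disjoint from the other series
  pool <- seq_len(params$n_locations)
  loc_list <- vector("list", n_cycles)
  for (cc in seq_len(n_cycles)) {
    o12 <- sample(pool, params$overlap_y1y2)
    o13 <- sample(setdiff(pool, o12), params$overlap_y1y3)
    o23 <- sample(setdiff(pool, c(o12, o13)), params$overlap_y2y3)
    free <- setdiff(pool, c(o12, o13, o23))
    t1 <- sample(free, params$locs_y1 - length(o12) - length(o13))
    free <- setdiff(free, t1)
    t2 <- sample(free, params$locs_y2 - length(o12) - length(o23))
    free <- setdiff(free, t2)
    t3 <- sample(free, params$locs_y3 - length(o13) - length(o23))
    L <- list(sort(c(o12, o13, t1)), sort(c(o12, o23, t2)),
              sort(c(o13, o23, t3)))
    loc_list[[cc]] <- data.frame(
      cycle = cc,
      series_year = rep(1:3, lengths(L)),
      year = cc + rep(0:2, lengths(L)),
      location = unlist(L)
    )
  }
  cycle_locs <- do.call(rbind, loc_list)

  checks <- draw_check_panel(params)

  # candidate cells: slot k of series-year s at each of the series' locations
  cand <- merge(cycle_locs, cycles, by = "cycle")
  k <- with(cand, ifelse(series_year == 1, n_entries,
                         ifelse(series_year == 2, n_keep2, n_keep3)))
  cand <- cand[rep(seq_len(nrow(cand)), k), c("cycle", "series_year", "year", "location")]
  cand$slot <- sequence(k)
  cand_cells <- data.frame(
    role = "candidate", cycle = cand$cycle, series_year = cand$series_year,
    slot = cand$slot, check_id = NA_character_, year = cand$year,
    location = cand$location,
    trial = trial_ids(cand$year, cand$location, cand$cycle),
    stringsAsFactors = FALSE
  )

  # check cells: every active check in every trial of its active years
  trials <- unique(cycle_locs)
  chk_rows <- lapply(seq_len(nrow(checks)), function(i) {
    act <- trials[trials$year >= checks$start_year[i] &
                  trials$year <= checks$end_year[i], , drop = FALSE]
    if (nrow(act) == 0L) return(NULL)
    data.frame(role = "check", cycle = act$cycle,
               series_year = act$series_year, slot = NA_integer_,
               check_id = checks$check_id[i], year = act$year,
               location = act$location,
               trial = trial_ids(act$year, act$location, act$cycle),
               stringsAsFactors = FALSE)
  })
  cells <- rbind(cand_cells, do.call(rbind, chk_rows))
  ord <- order(cells$year, cells$location, cells$cycle,
               cells$role, cells$slot, cells$check_id)
  cells <- cells[ord, , drop = FALSE]
  rownames(cells) <- NULL

  structure(list(params = params, cycles = cycles, cycle_locs = cycle_locs,
                 checks = checks, cells = cells),
            class = "vcu_structure")
}

# staggered check panel: evenly spread start years, geometric-ish spans with
# the requested mean, then a repair pass guaranteeing that every year hosts
# at least two active checks and that consecutive years share a check (the
# across-cycle connectivity that trend estimation relies on).
draw_check_panel <- function(params) {
  n <- params$n_checks
  ny <- params$n_years
  start <- floor(seq(1, ny, length.out = n) + 0.5)
  span <- pmax(2L, 1L + stats::rgeom(n, prob = 1 / params$check_span_years))
  end <- pmin(ny, start + span - 1L)
  # repair: coverage of >= 2 checks per year
  for (y in seq_len(ny)) {
    while (sum(start <= y & end >= y) < min(2L, n)) {
      below <- which(end < y)
      above <- which(start > y)
      if (length(below) && (!length(above) ||
          (y - max(end[below])) <= (min(start[above]) - y))) {
        i <- below[which.max(end[below])]
        end[i] <- y
      } else {
        i <- above[which.min(start[above])]
        start[i] <- y
      }
    }
  }
  # repair: consecutive years must share at least one check
  for (y in seq_len(ny - 1L)) {
    if (!any(start <= y & end >= y + 1L)) {
      i <- which(start <= y & end >= y)
      i <- i[which.max(end[i])]
      end[i] <- y + 1L
    }
  }
  # a check whose activity starts in year s >= 4 descends from the cycle
  # that finished testing in year s - 1 (i.e. the cycle starting s - 3)
  source_cycle <- ifelse(start - 3L >= 1L & start - 3L <= ny - 2L,
                         start - 3L, NA_integer_)
  data.frame(check_id = check_ids(n), start_year = start,
             end_year = end, source_cycle = as.integer(source_cycle),
             stringsAsFactors = FALSE)
}

#' @export
print.vcu_structure <- function(x, ...) {
  s <- structure_summary(x)
  cat(sprintf("VCU trial structure: %d years, %d cycles, %d locations\n",
              x$params$n_years, nrow(x$cycles), x$params$n_locations))
  cat(sprintf("  %d cells (%d candidate, %d check), %d trials, %d genotypes\n",
              s$observations, s$observations_candidate, s$observations_check,
              s$trials, s$genotypes))
  invisible(x)
}

#' Aggregate counts of a trial structure
#'
#' Tabulates the skeleton the way registration series are usually
#' characterised: numbers of observations (split candidate/check), years,
#' locations, year-by-location combinations, trials, genotypes, and
#' genotype-by-year / -by-location / -by-year-by-location combinations.
#' Genotype identities in survivor slots are resolved with the default
#' (rank-order) slot filling, so counts do not depend on a selection outcome.
#'
#' @param structure a `vcu_structure`.
#' @return A list of class `vcu_structure_summary` of named counts.
#' @export
structure_summary <- function(structure) {
  res <- resolve_cells(structure, default_selection(structure))
  cells <- res$cells
  gy <- paste(cells$genotype, cells$year)
  gl <- paste(cells$genotype, cells$location)
  gyl <- paste(cells$genotype, cells$year, cells$location)
  out <- list(
    observations = nrow(cells),
    observations_candidate = sum(cells$role == "candidate"),
    observations_check = sum(cells$role == "check"),
    years = length(unique(cells$year)),
    locations = length(unique(cells$location)),
    year_location = length(unique(paste(cells$year, cells$location))),
    trials = length(unique(cells$trial)),
    genotypes = length(unique(cells$genotype)),
    genotype_year = length(unique(gy)),
    genotype_location = length(unique(gl)),
    genotype_year_location = length(unique(gyl))
  )
  class(out) <- "vcu_structure_summary"
  out
}

#' @export
print.vcu_structure_summary <- function(x, ...) {
  df <- data.frame(count = unlist(x))
  print(df)
  invisible(x)
}

# rank-order slot filling: survivor slot k holds entry k.  Used wherever
# counts must not depend on a phenotype-driven selection outcome.
default_selection <- function(structure) {
  sel <- lapply(seq_len(nrow(structure$cycles)), function(cc) {
    ids <- entry_ids(cc, structure$cycles$n_entries[cc])
    list(kept2 = ids[seq_len(structure$cycles$n_keep2[cc])],
         kept3 = ids[seq_len(structure$cycles$n_keep3[cc])])
  })
  structure(sel, mode = "default")
}

# map every cell to a genotype id and a first-test year, given a selection
# outcome; former-candidate checks take over the identity of the
# best-ranked, not yet used year-3 survivor of their source cycle.
resolve_cells <- function(structure, selection,
                          check_assignment = NULL) {
  cells <- structure$cells
  cyc <- structure$cycles
  if (is.null(check_assignment)) {
    check_assignment <- assign_check_genotypes(structure, selection)
  }
  genotype <- character(nrow(cells))
  first_year <- integer(nrow(cells))

  is_cand <- cells$role == "candidate"
  cc <- cells$cycle[is_cand]
  sy <- cells$series_year[is_cand]
  slot <- cells$slot[is_cand]
  g <- character(sum(is_cand))
  for (s in 1:3) {
    idx <- which(sy == s)
    if (!length(idx)) next
    g[idx] <- vapply(idx, function(i) {
      cyc_i <- cc[i]
      if (s == 1L) entry_ids(cyc_i, structure$cycles$n_entries[cyc_i])[slot[i]]
      else if (s == 2L) selection[[cyc_i]]$kept2[slot[i]]
      else selection[[cyc_i]]$kept3[slot[i]]
    }, character(1))
  }
  genotype[is_cand] <- g
  first_year[is_cand] <- cyc$start_year[cc]

  idx_chk <- which(!is_cand)
  if (length(idx_chk)) {
    gmap <- check_assignment$genotype
    fmap <- check_assignment$first_year
    genotype[idx_chk] <- gmap[cells$check_id[idx_chk]]
    first_year[idx_chk] <- fmap[cells$check_id[idx_chk]]
  }
  cells$genotype <- genotype
  cells$first_year <- first_year
  list(cells = cells, check_assignment = check_assignment)
}

# one genotype id per check: former candidates re-use a survivor identity
assign_check_genotypes <- function(structure, selection) {
  checks <- structure$checks[order(structure$checks$start_year,
                                   structure$checks$check_id), ]
  genotype <- stats::setNames(checks$check_id, checks$check_id)
  first_year <- stats::setNames(checks$start_year, checks$check_id)
  used <- character(0)
  for (i in seq_len(nrow(checks))) {
    sc <- checks$source_cycle[i]
    if (is.na(sc)) next
    avail <- setdiff(selection[[sc]]$kept3, used)
    if (!length(avail)) next
    genotype[checks$check_id[i]] <- avail[1]
    first_year[checks$check_id[i]] <- structure$cycles$start_year[sc]
    used <- c(used, avail[1])
  }
  list(genotype = genotype, first_year = first_year)
}

#' Connectivity of the check panel across years
#'
#' Trend estimation compares genotypes that entered in different years, which
#' is only possible if the data are connected across cycles through shared
#' check varieties.  This helper verifies the sufficient condition that every
#' pair of consecutive calendar years shares at least one active check.
#'
#' @param structure a `vcu_structure`.
#' @return `TRUE` if consecutive years are linked by checks throughout.
#' @export
check_connectivity <- function(structure) {
  ck <- structure$checks
  ny <- structure$params$n_years
  all(vapply(seq_len(ny - 1L), function(y) {
    any(ck$start_year <= y & ck$end_year >= y + 1L)
  }, logical(1)))
}
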