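# data for a cycle's first year built directly: y = G + L + noise
year1_toy <- function(G, locs = 2, sd_noise = 0, check = NULL) {
  g <- names(G)
  d <- expand.grid(genotype = g, location = seq_len(locs),
                   stringsAsFactors = FALSE)
  d$role <- ifelse(d$genotype %in% check, "check", "candidate")
  d$y <- G[d$genotype] + 0.5 * d$location +
    stats::rnorm(nrow(d), 0, sd_noise)
  d
}

test_that("noise-free year-1 selection ranks by the simulated effects", {
  G <- c(a = 1, b = 3, c = 2)
  vc <- variance_components(genotype = 13.27, residual = 0.01)
  d <- year1_toy(G, locs = 2)
  expect_equal(select_year1(d, 2, vc), c("b", "c"))
  expect_equal(select_year1(d, 1, vc), "b")
  expect_error(select_year1(d, 5, vc), "exceeds")
})

test_that("year-1 BLUPs match the dense Henderson equations", {
  set.seed(8)
  vc <- bsa_variance_components()
  G <- stats::setNames(rnorm(4, 0, 3), c("g1", "g2", "g3", "g4"))
  d <- year1_toy(G, locs = 3, sd_noise = 2, check = "g4")
  cvc <- vcusim:::confound_vc_year1(vc)
  sparse <- vcusim:::solve_mme_known(
    d$y, list(location = factor(d$location), genotype = factor(d$genotype)),
    cvc$vars, cvc$ve)
  dense <- dense_mme_blup(d$y, list(location = d$location,
                                    genotype = d$genotype),
                          cvc$vars, cvc$ve)
  expect_equal(sparse$genotype, dense$genotype, tolerance = 1e-8)
  expect_equal(sparse$location, dense$location, tolerance = 1e-8)
})

test_that("year-2 selection ranks noise-free data by genotype effect and is symmetric", {
  vc <- variance_components(genotype = 10, residual = 0.01)
  G <- c(p = 2, q = -2, chk = 0)
  d <- expand.grid(genotype = names(G), location = 1:2, year = 1:2,
                   stringsAsFactors = FALSE)
  d$role <- ifelse(d$genotype == "chk", "check", "candidate")
  d$y <- G[d$genotype]
  expect_equal(select_year2(d, 1, vc), "p")
  # swapping the two candidates' effects flips the selection
  d2 <- d
  d2$y <- c(p = -2, q = 2, chk = 0)[d2$genotype]
  expect_equal(select_year2(d2, 1, vc), "q")
})

test_that("year-2 BLUPs match a dense mixed-model-equations solve", {
  set.seed(21)
  vc <- bsa_variance_components()
  d <- expand.grid(genotype = paste0("g", 1:5), location = 1:3, year = 1:2,
                   stringsAsFactors = FALSE)
  d$role <- "candidate"
  d$y <- 80 + rnorm(nrow(d), 0, 6)
  cvc <- vcusim:::confound_vc_year2(vc)
  keys <- list(year = factor(d$year), location = factor(d$location),
               genotype = factor(d$genotype),
               year_location = factor(vcusim:::ekey(d$year, d$location)),
               genotype_location = factor(vcusim:::ekey(d$genotype, d$location)),
               genotype_year = factor(vcusim:::ekey(d$genotype, d$year)))
  sparse <- vcusim:::solve_mme_known(d$y, keys, cvc$vars, cvc$ve)
  dense <- dense_mme_blup(
    d$y,
    list(year = d$year, location = d$location, genotype = d$genotype,
         year_location = vcusim:::ekey(d$year, d$location),
         genotype_location = vcusim:::ekey(d$genotype, d$location),
         genotype_year = vcusim:::ekey(d$genotype, d$year)),
    cvc$vars, cvc$ve)
  expect_equal(sparse$genotype, dense$genotype, tolerance = 1e-8)
})

test_that("selection under overwhelming noise degenerates to random", {
  vc <- variance_components(genotype = 1, residual = 1e6)
  set.seed(99)
  sel_G <- replicate(400, {
    G <- stats::setNames(rnorm(4), paste0("g", 1:4))
    d <- year1_toy(G, locs = 2, sd_noise = 1e3)
    mean(G[select_year1(d, 2, vc)])
  })
  # selection differential indistinguishable from zero
  expect_lt(abs(mean(sel_G)) / (sd(sel_G) / sqrt(length(sel_G))), 4)
})

test_that("random selection is uniform, seeded and size-checked", {
  e <- paste0("g", 1:6)
  expect_equal(select_random(e, 6), sort(e))
  expect_identical(select_random(e, 3, seed = 7),
                   select_random(e, 3, seed = 7))
  expect_error(select_random(e, 7), "exceeds")
})

test_that("BLUP selection yields a positive selection differential", {
  fx <- make_fixture("small")
  truth <- fx$simulation$truth
  sel <- truth$selection
  st <- fx$structure
  kept <- unlist(lapply(sel, `[[`, "kept2"))
  all_entries <- unlist(lapply(st$cycles$cycle, function(cc) {
    vcusim:::entry_ids(cc, st$cycles$n_entries[cc])
  }))
  culled <- setdiff(all_entries, kept)
  H <- truth$effects$genotype
  expect_gt(mean(H[kept]), 0)
  expect_lt(mean(H[culled]), 0)
  expect_gt(mean(H[kept]), mean(H[culled]))
})

test_that("selection outcomes are nested and sized to the survivor slots", {
  fx <- make_fixture("small")
  sel <- fx$simulation$truth$selection
  cyc <- fx$structure$cycles
  for (cc in cyc$cycle) {
    entries <- vcusim:::entry_ids(cc, cyc$n_entries[cc])
    expect_length(sel[[cc]]$kept2, cyc$n_keep2[cc])
    expect_length(sel[[cc]]$kept3, cyc$n_keep3[cc])
    expect_true(all(sel[[cc]]$kept3 %in% sel[[cc]]$kept2))
    expect_true(all(sel[[cc]]$kept2 %in% entries))
  }
})
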