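test_that("zero variances and zero slopes give a constant response", {
  fx <- make_fixture("tiny")
  vc0 <- variance_components(mu = 200)
  sim <- simulate_run(fx$structure, vc0, mode = "random", seed = 1)
  expect_equal(sim$data$y, rep(200, nrow(sim$data)))
})

test_that("trend slopes enter the response as plain regressions", {
  vc <- variance_components(beta = 0.5, gamma = 0.25, mu = 100)
  eff <- vcusim:::new_effect_set(vc)
  rows <- data.frame(genotype = c("a", "b"), year = c(4L, 4L),
                     first_year = c(1L, 11L), location = 1L,
                     trial = c("t1", "t1"))
  out <- vcusim:::resolve_y(rows, eff, vc)
  expect_equal(out$y[2] - out$y[1], 0.5 * 10)      # beta * delta r
  expect_equal(out$y[1], 100 + 0.25 * 4 + 0.5 * 1) # mu + gamma t + beta r
})

test_that("responses reconstruct exactly from the stored truth effects", {
  fx <- make_fixture("small")
  sim <- simulate_run(fx$structure, fx$vc, mode = "blup", seed = 5,
                      keep_components = TRUE)
  d <- sim$data
  comp_cols <- paste0("eff_", c(
    "mu", "trend_t", "trend_r", "year", "location", "genotype",
    "year_location", "trial", "genotype_location", "genotype_year",
    "genotype_year_location", "residual"))
  expect_equal(rowSums(d[comp_cols]), d$y)
  # component columns agree with the truth store
  expect_equal(d$eff_genotype,
               unname(sim$truth$effects$genotype[d$genotype]))
  expect_equal(d$eff_year,
               unname(sim$truth$effects$year[as.character(d$year)]))
})

test_that("cells in the same year and location share environment effects", {
  fx <- make_fixture("small")
  sim <- simulate_run(fx$structure, fx$vc, mode = "blup", seed = 5,
                      keep_components = TRUE)
  d <- sim$data
  key <- paste(d$year, d$location)
  spread <- function(x) max(x) - min(x)
  expect_true(all(tapply(d$eff_year_location, key, spread) == 0))
  expect_true(all(tapply(d$eff_year, d$year, spread) == 0))
  expect_true(all(tapply(d$eff_location, d$location, spread) == 0))
  # duplicate check rows within a year-location share the three-way effect
  dup <- d[paste(d$genotype, d$year, d$location) %in%
             names(which(table(paste(d$genotype, d$year, d$location)) > 1)), ]
  if (nrow(dup)) {
    expect_true(all(tapply(dup$eff_genotype_year_location,
                           paste(dup$genotype, dup$year, dup$location),
                           spread) == 0))
    # but distinct plot errors per trial
    expect_true(any(tapply(dup$eff_residual,
                           paste(dup$genotype, dup$year, dup$location),
                           spread) > 0))
  }
})

test_that("realized effect variances recover their parameters", {
  vc <- bsa_variance_components()
  set.seed(77)
  eff <- vcusim:::new_effect_set(vc)
  h <- vcusim:::effect_get(eff, "genotype", paste0("g", 1:10000))
  n <- length(h)
  # chi-square 99.9% band for the sample variance of normal draws
  band <- vc$sigma2["genotype"] *
    stats::qchisq(c(5e-4, 1 - 5e-4), n - 1) / (n - 1)
  expect_gt(stats::var(h), band[1])
  expect_lt(stats::var(h), band[2])
})

test_that("check-effect transfer copies genotype and location terms only", {
  vc <- bsa_variance_components()
  set.seed(3)
  eff <- vcusim:::new_effect_set(vc)
  h <- vcusim:::effect_get(eff, "genotype", "cand1")
  gl <- vcusim:::effect_get(eff, "genotype_location",
                            vcusim:::ekey("cand1", 1:3))
  transfer_check_effects(eff, "cand1", "chk1")
  expect_equal(vcusim:::effect_get(eff, "genotype", "chk1"), h)
  expect_equal(vcusim:::effect_get(eff, "genotype_location",
                                   vcusim:::ekey("chk1", 1:3)), gl)
  # year-linked effects are NOT shared
  gy_c <- vcusim:::effect_get(eff, "genotype_year", vcusim:::ekey("cand1", 5))
  gy_k <- vcusim:::effect_get(eff, "genotype_year", vcusim:::ekey("chk1", 5))
  expect_false(isTRUE(all.equal(gy_c, gy_k)))
  # transferring onto an assigned check is a consistency error
  expect_error(transfer_check_effects(eff, "cand2", "chk1"),
               class = "vcu_consistency_error")
})

test_that("without transfer, check effects are independent of candidates", {
  vc <- variance_components(genotype = 4)
  set.seed(42)
  pairs <- t(replicate(2000, {
    eff <- vcusim:::new_effect_set(vc)
    c(vcusim:::effect_get(eff, "genotype", "cand"),
      vcusim:::effect_get(eff, "genotype", "chk"))
  }))
  expect_lt(abs(stats::cor(pairs[, 1], pairs[, 2])), 0.08)
  # with transfer the correlation is exactly 1 and the variance is preserved
  expect_lt(abs(stats::var(pairs[, 2]) - 4) / 4, 0.15)
})

test_that("simulate_cycle_full covers all entries in all three years", {
  fx <- make_fixture("small")
  eff <- vcusim:::new_effect_set(fx$vc)
  set.seed(1)
  full <- simulate_cycle_full(fx$structure, 2, fx$vc, eff)
  n <- fx$structure$cycles$n_entries[2]
  locs <- fx$structure$cycle_locs
  for (s in 1:3) {
    nl <- sum(locs$cycle == 2 & locs$series_year == s)
    expect_equal(sum(full$series_year == s), n * nl)
    expect_equal(length(unique(full$genotype[full$series_year == s])), n)
  }
  expect_error(simulate_cycle_full(fx$structure, 99, fx$vc, eff),
               class = "vcu_config_error")
})

test_that("assembly demands a complete selection outcome", {
  fx <- make_fixture("tiny")
  eff <- vcusim:::new_effect_set(fx$vc)
  sel <- vcusim:::default_selection(fx$structure)
  sel[[1]]$kept3 <- character(0)
  expect_error(assemble_dataset(fx$structure, fx$vc, eff, sel),
               "survivor slots")
})

test_that("dataset row count equals the structure cell count", {
  fx <- make_fixture("small")
  expect_equal(nrow(fx$simulation$data), nrow(fx$structure$cells))
})
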