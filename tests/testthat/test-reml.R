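test_that("balanced one-way layout reproduces the closed-form REML solution", {
  # 3 groups x 4 replicates with fixed printed numbers
  y <- c(10.1, 11.2, 9.8, 10.6,
         13.0, 12.4, 13.5, 12.9,
         8.9, 9.6, 9.1, 9.4)
  g <- rep(c("A", "B", "C"), each = 4)
  d <- data.frame(y = y, g = g)
  fit <- reml_fit(d, model_spec(fixed = character(0), random = "g"))
  m <- tapply(y, g, mean)
  msw <- sum((y - m[g])^2) / (12 - 3)
  msb <- 4 * sum((m - mean(y))^2) / 2
  expect_equal(unname(fit$vc["residual"]), msw, tolerance = 1e-6)
  expect_equal(unname(fit$vc["g"]), max(0, (msb - msw) / 4),
               tolerance = 1e-5)
})

test_that("sparse fit agrees with lme4 on a crossed trend model", {
  skip_if_not_installed("lme4")
  fx <- make_fixture("small")
  d <- fx$simulation$data
  fit <- reml_fit(d, trend_model_spec(), start = fx$vc)
  dd <- within(d, {
    t <- year; r <- first_year
    yl <- paste(year, location)
    gl <- paste(genotype, location)
    gy <- paste(genotype, year)
  })
  lf <- lme4::lmer(
    y ~ t + r + (1 | year) + (1 | location) + (1 | genotype) + (1 | yl) +
      (1 | trial) + (1 | gl) + (1 | gy),
    data = dd, REML = TRUE,
    control = lme4::lmerControl(calc.derivs = FALSE))
  vc_l <- as.data.frame(lme4::VarCorr(lf))
  ref <- stats::setNames(vc_l$vcov, vc_l$grp)
  expect_equal(unname(fit$vc["genotype"]), unname(ref["genotype"]),
               tolerance = 1e-4)
  expect_equal(unname(fit$vc["year_location"]), unname(ref["yl"]),
               tolerance = 1e-4)
  expect_equal(unname(fit$vc["residual"]), unname(ref["Residual"]),
               tolerance = 1e-4)
  expect_equal(fit$loglik, -lme4::REMLcrit(lf) / 2, tolerance = 1e-6)
  co <- summary(lf)$coefficients
  expect_equal(trend_slopes(fit),
               c(beta = unname(co["r", "Estimate"]),
                 gamma = unname(co["t", "Estimate"])), tolerance = 1e-4)
  expect_equal(fit$fixed$se, unname(co[, "Std. Error"]), tolerance = 1e-3)
})

test_that("REML is invariant to translating the response", {
  d <- random_tiny_instance(11)
  spec <- model_spec(fixed = character(0), random = c("g1", "g2"))
  f1 <- reml_fit(d, spec)
  d2 <- d; d2$y <- d$y + 100
  f2 <- reml_fit(d2, spec)
  expect_equal(f1$vc, f2$vc, tolerance = 1e-5)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f2$fixed$estimate[1] - f1$fixed$estimate[1], 100,
               tolerance = 1e-5)
})

test_that("a genotype variance estimated at zero fully shrinks its BLUPs", {
  set.seed(12)
  n <- 60
  d <- data.frame(y = rnorm(n),  # no group signal at all
                  g1 = sample(paste0("u", 1:6), n, TRUE),
                  g2 = sample(paste0("v", 1:5), n, TRUE))
  fit <- reml_fit(d, model_spec(fixed = character(0), random = c("g1", "g2")))
  shrunk <- names(fit$vc)[fit$vc < 1e-8]
  skip_if(length(shrunk) == 0)  # seed chosen to hit the boundary
  for (s in intersect(shrunk, names(fit$blup))) {
    expect_lt(max(abs(fit$blup[[s]])), 1e-5)
  }
})

test_that("fit BLUPs solve the mixed-model equations at the estimates", {
  d <- random_tiny_instance(4)
  spec <- model_spec(fixed = character(0), random = c("g1", "g2"))
  fit <- reml_fit(d, spec)
  dense <- dense_mme_blup(d$y, list(g1 = d$g1, g2 = d$g2),
                          c(fit$vc["g1"], fit$vc["g2"]),
                          fit$vc["residual"])
  expect_equal(fit$blup$g1, dense$g1, tolerance = 1e-6)
  expect_equal(fit$blup$g2, dense$g2, tolerance = 1e-6)
})

test_that("BLUPs approach the true effects as noise vanishes", {
  set.seed(5)
  G <- stats::setNames(rnorm(8, 0, 2), paste0("g", 1:8))
  d <- expand.grid(g1 = names(G), rep = 1:6, stringsAsFactors = FALSE)
  d$y <- 10 + G[d$g1] + rnorm(nrow(d), 0, 0.01)
  fit <- reml_fit(d, model_spec(fixed = character(0), random = "g1"))
  expect_gt(stats::cor(fit$blup$g1[names(G)], G), 0.999)
  expect_lt(max(abs(fit$blup$g1[names(G)] - (G - mean(G)))), 0.05)
})

test_that("the three-way factor collapses when no duplicates exist", {
  fx <- make_fixture("small")
  d <- dedup_checks(fx$simulation$data, seed = 1)
  expect_message(
    fit <- reml_fit(d, trend_model_spec(separate_three_way = TRUE),
                    start = fx$vc),
    "collapsing")
  expect_false("genotype_year_location" %in% names(fit$vc))
})

test_that("confounded first-year and testing-year covariates are rejected", {
  set.seed(2)
  d <- expand.grid(genotype = paste0("g", 1:10), location = 1:3,
                   stringsAsFactors = FALSE)
  d$year <- as.integer(sub("g", "", d$genotype))  # each genotype one year
  d$first_year <- d$year                          # r identical to t
  d$trial <- paste(d$year, d$location)
  d$y <- rnorm(nrow(d), 80, 5)
  expect_error(reml_fit(d, trend_model_spec()),
               class = "vcu_estimability_error")
})

test_that("design matrices index observed factor levels only", {
  d <- data.frame(y = 1:4, year = c(1, 1, 2, 2), location = c(1, 2, 1, 2),
                  genotype = "g", trial = "t", first_year = 1)
  des <- build_design(d, model_spec(fixed = "t",
                                    random = c("year", "year:location")))
  expect_equal(dim(des$Z[["year"]]), c(4L, 2L))
  expect_equal(Matrix::rowSums(des$Z[["year"]]), rep(1, 4))
  # only observed year-location combinations get columns
  expect_equal(ncol(des$Z[["year:location"]]), 4L)
  expect_equal(colnames(des$X), c("(Intercept)", "t"))
})
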