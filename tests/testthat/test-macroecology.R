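test_that("regime regressions recover an exact Boltzmann line", {
  set.seed(2)
  tc <- runif(400, -1.5, 31)
  x <- 1 / (boltzmann_k() * (tc + 273.15))
  rich <- exp(10 - 0.32 * x)
  fit <- suppressWarnings(fit_thermal_regimes(rich, tc))  # exact fit
  expect_equal(fit$slope, rep(-0.32, 4), tolerance = 1e-9)
  expect_equal(fit$r_squared, rep(1, 4), tolerance = 1e-9)
  expect_equal(fit$regime,
               c("global", "T < 11", "11 <= T < 19", "T >= 19"))
  expect_equal(sum(fit$n[-1]), fit$n[1])
})

test_that("the inverse thermal energy axis is computed in kelvin", {
  x19 <- 1 / (boltzmann_k() * (19 + 273.15))
  expect_equal(x19, 39.72, tolerance = 1e-3)
})

test_that("regime fits equal the least-squares oracle on noisy data", {
  set.seed(5)
  tc <- runif(300, -1, 30)
  x <- 1 / (boltzmann_k() * (tc + 273.15))
  rich <- exp(8 - 0.4 * x + rnorm(300, 0, 0.3))
  fit <- fit_thermal_regimes(rich, tc, breakpoints = c(11, 19))
  sel <- tc >= 11 & tc < 19
  oracle <- stats::lm(log(rich[sel]) ~ x[sel])
  row <- fit[fit$regime == "11 <= T < 19", ]
  expect_equal(row$slope, unname(coef(oracle)[2]), tolerance = 1e-12)
  expect_equal(row$intercept, unname(coef(oracle)[1]), tolerance = 1e-12)
  expect_equal(row$r_squared, summary(oracle)$r.squared,
               tolerance = 1e-12)
  ## zero and missing richness are excluded, not log-transformed
  rich[1:5] <- 0; rich[6] <- NA
  fit2 <- fit_thermal_regimes(rich, tc)
  expect_equal(fit2$n[1], 294)
})

test_that("breakpoint search finds a strong change point", {
  set.seed(11)
  tc <- runif(600, -1, 31)
  x <- 1 / (boltzmann_k() * (tc + 273.15))
  x15 <- 1 / (boltzmann_k() * (15 + 273.15))
  y <- ifelse(tc >= 15, 5 - 0.3 * (x - x15), 5 + 1 * (x - x15)) +
    rnorm(600, 0, 0.05)
  fit <- search_thermal_breakpoints(exp(y), tc, grid = seq(6, 26, 1),
                                    min_gap = 3)
  bp <- attr(fit, "breakpoints")
  expect_true(any(abs(bp - 15) <= 2))
})

test_that("single-variable power behaves at its extremes", {
  set.seed(3)
  y <- runif(1000, 10, 200)
  expect_equal(suppressWarnings(single_variable_power(y, y)), 1,
               tolerance = 1e-9)
  expect_lt(single_variable_power(y, sample(y)), 0.05)
  expect_equal(single_variable_power(y, rep(3, 1000)), 0)
  expect_error(single_variable_power(y[1:5], y[1:5]), "min_n")
})

test_that("a noiseless thermal response puts temperature on top", {
  set.seed(7)
  n <- 500
  tc <- runif(n, -1, 31)
  rich <- 200 * exp(-0.05 * (30 - tc))
  d <- data.frame(T = tc, junk = rnorm(n), wind = runif(n, 2, 12))
  tab <- single_variable_power_table(rich, d, c("T", "junk", "wind"))
  expect_equal(tab$predictor[1], "T")
  expect_gt(tab$r_squared[1], 0.99)
})

test_that("rarefied richness reduces to totals and matches exhaustive
           expectation on a toy", {
  rec <- make_records(10,
                      scientificName = c("a", "a", "b", "c", "a", "b",
                                         "d", "d", "e", "a"),
                      decimalLatitude = 1:10)   # 10 distinct samples
  strata <- rep(c("N", "S"), each = 5)
  ## drawing every sample once returns the observed richness
  res <- rarefied_raw_richness(rec, strata, n_per_stratum = 5, n_reps = 1,
                               seed = 1)
  expect_equal(res$mean_richness[res$stratum == "N"], 3)  # a, b, c
  expect_equal(res$mean_richness[res$stratum == "S"], 4)  # a, b, d, e
  expect_true(all(is.na(res$sd_richness)))  # undefined for one repetition

  ## exhaustive oracle: expected richness over all C(5, 2) subsets
  north <- c("a", "a", "b", "c", "a")
  combos <- utils::combn(5, 2)
  exp_rich <- mean(apply(combos, 2, function(ix)
    length(unique(north[ix]))))
  res2 <- rarefied_raw_richness(rec, strata, n_per_stratum = 2,
                                n_reps = 4000, seed = 2)
  expect_equal(res2$mean_richness[res2$stratum == "N"], exp_rich,
               tolerance = 0.05)
  ## mean rarefied richness grows with the draw size
  res3 <- rarefied_raw_richness(rec, strata, n_per_stratum = 4,
                                n_reps = 4000, seed = 3)
  expect_gt(res3$mean_richness[1], res2$mean_richness[1])

  ## under-filled strata are excluded and reported
  res4 <- rarefied_raw_richness(rec, strata, n_per_stratum = 6,
                                n_reps = 5, seed = 4)
  expect_equal(nrow(res4), 0L)
  expect_setequal(attr(res4, "excluded"), c("N", "S"))
})

test_that("observed ranges report extremes and medians", {
  expect_equal(observed_range(17), c(min = 17, max = 17, median = 17))
  expect_equal(observed_range(c(3, 12, 25)),
               c(min = 3, max = 25, median = 12))
  expect_error(observed_range(NA_real_), "no matchable")
})

test_that("species ranges match environmental and latitudinal extremes", {
  env <- toy_env()
  ## temperature varies by latitude row only: 5, 10, 15, 20 degrees
  env$fields$T <- array(rep(c(5, 10, 15, 20), each = 12), c(12, 4, 3))
  rec <- make_records(3, decimalLatitude = c(0.5, 1.5, 3.5), month = 1L)
  rr <- species_observed_ranges(rec, env, var = "T")
  expect_equal(rr$min, 5)
  expect_equal(rr$max, 20)
  expect_equal(rr$median, 10)
  lr <- species_observed_ranges(rec, env, var = "latitude")
  expect_equal(lr$min, 0.5)
  expect_equal(lr$max, 3.5)
})

test_that("range-overlap curves equal exhaustive per-value counting", {
  ranges <- data.frame(species_id = c("a", "b", "c"),
                       min = c(0, 5, 8), max = c(10, 15, 20))
  cur <- range_overlap_curves(ranges, c(0, 9))
  expect_equal(cur$overlap, c(1, 3))
  expect_equal(cur$mean_range_size[1], 10)
  expect_equal(cur$mean_range_size[2], mean(c(10, 10, 12)))
  ## one species: the overlap curve is the indicator of its range
  one <- range_overlap_curves(ranges[1, ], seq(-5, 15, 5))
  expect_equal(one$overlap, c(0, 1, 1, 1, 0))
  ## exhaustive oracle on random range sets
  set.seed(13)
  for (i in 1:50) {
    n <- sample(2:20, 1)
    lo <- runif(n, 0, 20); hi <- lo + runif(n, 0, 15)
    rg <- data.frame(min = lo, max = hi)
    grid <- runif(20, -2, 36)
    cur2 <- range_overlap_curves(rg, grid)
    oracle <- vapply(grid, function(v) sum(lo <= v & v <= hi), integer(1))
    expect_identical(cur2$overlap, oracle)
  }
})

test_that("the range null model conserves species counts and flags
           gradient edges", {
  set.seed(19)
  n <- 2000
  values <- runif(n, 0, 30)                  # uniform pooled environment
  species <- sample(paste0("s", 1:40), n, replace = TRUE)
  nm <- range_null_model(values, species, n_runs = 60, seed = 4)
  nm2 <- range_null_model(values, species, n_runs = 60, seed = 4)
  expect_identical(nm, nm2)                  # seeded determinism
  ## centre of the gradient: overlap flat near the species total, unflagged
  centre <- nm$overlap$value > 10 & nm$overlap$value < 20
  expect_true(all(!nm$overlap$edge_flag[centre]))
  expect_gt(min(nm$overlap$mean[centre]), 35)
  ## extreme edges decline and are flagged
  expect_true(nm$overlap$edge_flag[1])
  expect_true(nm$overlap$edge_flag[nrow(nm$overlap)])
  expect_lt(nm$overlap$mean[1], nm$center_overlap)
})

test_that("a single-species null model is degenerate but conserves its
           records", {
  values <- c(1, 5, 9)
  expect_warning(nm <- range_null_model(values, rep("only", 3),
                                        n_runs = 5, seed = 1),
                 "unstable")
  ## every run sees the same single range [1, 9]
  expect_true(all(nm$overlap$lower == nm$overlap$upper))
})
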