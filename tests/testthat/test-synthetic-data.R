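test_that("environment generation is deterministic and bounded", {
  g <- grid_spec(20, 8, lat_min = -10, lon_min = 0)
  e1 <- generate_environment(g, seed = 5)
  e2 <- generate_environment(g, seed = 5)
  expect_identical(e1$fields, e2$fields)
  e3 <- generate_environment(g, seed = 6)
  expect_false(identical(e1$fields$T, e3$fields$T))

  tv <- env_field(e1, "T")
  expect_gte(min(tv, na.rm = TRUE), -1.8)
  expect_lte(max(tv, na.rm = TRUE), 32)
  expect_true(all(env_field(e1, "MLD") > 0, na.rm = TRUE))
  for (v in c("NO3", "PO4", "SiOH4", "Chl"))
    expect_true(all(env_field(e1, v) >= 0, na.rm = TRUE))
})

test_that("zero seasonal amplitude gives identical monthly temperatures", {
  g <- grid_spec(12, 6, lat_min = 0, lon_min = 0)
  env <- generate_environment(g, env_config(t_seasonal = c(0, 0)), seed = 3)
  tv <- env_field(env, "T")
  for (m in 2:12) expect_equal(tv[m, , ], tv[1, , ])
})

test_that("temperature declines poleward and mid-latitude seasonality
           exceeds tropical seasonality", {
  env <- small_env()
  tv <- env_field(env, "T")
  row_mean <- apply(tv, 2, mean, na.rm = TRUE)
  n <- length(row_mean)
  centre <- (n + 1) / 2
  ## monotone decline away from the central (equatorial) row
  expect_gt(row_mean[ceiling(centre)], row_mean[n])
  expect_gt(row_mean[floor(centre)], row_mean[1])
  row_amp <- apply(apply(tv, c(1, 2), mean, na.rm = TRUE), 2,
                   function(v) diff(range(v)))
  mid <- round(centre + n / 4)
  expect_gt(row_amp[mid], row_amp[round(centre)])
})

test_that("land mask is consistent across months and variables", {
  g <- grid_spec(10, 6, lat_min = 0, lon_min = 0)
  env <- generate_environment(g, env_config(n_land_cols = 2), seed = 9)
  na_T <- is.na(env_field(env, "T"))
  expect_true(any(na_T))
  for (v in env_vars(env)) expect_identical(is.na(env_field(env, v)), na_T)
  for (m in 2:12) expect_identical(na_T[m, , ], na_T[1, , ])
})

test_that("species pools are seeded, unimodal, and validated", {
  cfg <- niche_config(predictors = list(T = list(opt = c(20, 20),
                                                 breadth = c(4, 4))),
                      max_prob = c(1, 1))
  pool <- generate_species_pool(1, cfg, seed = 1)
  env <- small_env()
  suit <- species_suitability(pool[1, ], env)
  tv <- env_field(env, "T")
  best <- which.max(suit)
  expect_equal(abs(tv[best] - 20), min(abs(tv - 20), na.rm = TRUE),
               tolerance = 1e-9)

  p1 <- generate_species_pool(5, niche_config(), seed = 1)
  p2 <- generate_species_pool(5, niche_config(), seed = 2)
  expect_false(any(p1$opt_T == p2$opt_T))
  expect_identical(p1, generate_species_pool(5, niche_config(), seed = 1))

  expect_error(niche_config(predictors = list(
    T = list(opt = c(0, 30), breadth = c(0, 4)))), "breadth")
})

test_that("a spread-out pool produces latitudinally varying stacked
           suitability", {
  env <- small_env()
  cfg <- niche_config(predictors = list(T = list(opt = c(0, 30),
                                                 breadth = c(3, 6))),
                      max_prob = c(1, 1))
  pool <- generate_species_pool(50, cfg, seed = 8)
  stacked <- Reduce(`+`, lapply(seq_len(50), function(i)
    species_suitability(pool[i, ], env)))
  by_row <- apply(stacked, 2, mean, na.rm = TRUE)
  expect_gt(max(by_row) / min(by_row), 1.5)
})

test_that("metabolic pools realise the configured activation energy", {
  env <- small_env()
  tv <- env_field(env, "T")
  tcells <- tv[!is.na(tv)]

  flat <- generate_metabolic_pool(400, 0, env, seed = 2)
  s0 <- true_overlap(flat, tcells)
  x <- 1 / (boltzmann_k() * (tcells + 273.15))
  expect_lt(abs(coef(stats::lm(log(s0) ~ x))[2]), 0.02)

  pool <- generate_metabolic_pool(500, 0.32, env, seed = 3)
  s <- true_overlap(pool, tcells)
  slope <- coef(stats::lm(log(s) ~ x))[2]
  expect_equal(unname(slope), -0.32, tolerance = 0.01)
  expect_equal(attr(pool, "expected_slope"), -0.32, tolerance = 0.005)
})

test_that("doubling a metabolic pool shifts the intercept by log(2) and
           keeps the slope", {
  env <- small_env()
  p1 <- generate_metabolic_pool(250, 0.32, env, seed = 4)
  p2 <- generate_metabolic_pool(500, 0.32, env, seed = 4)
  expect_equal(attr(p2, "intercept") - attr(p1, "intercept"), log(2),
               tolerance = 1e-6)
  expect_equal(attr(p1, "expected_slope"), attr(p2, "expected_slope"),
               tolerance = 1e-6)
})

test_that("occurrence sampling concentrates records in the biased basin", {
  env <- small_env()
  g <- env$grid
  pool <- generate_metabolic_pool(60, 0.32, env, seed = 5)
  eff <- effort_model(g, "biased", env = env, seed = 6)
  occ <- sample_occurrences(pool, env, eff, 4000, seed = 7)
  basin <- attr(eff, "basin_cols")
  cells <- latlon_to_cell(g, occ$decimalLatitude, occ$decimalLongitude)
  frac <- mean(cells$lon_idx %in% basin)
  expect_equal(frac, 0.49, tolerance = 0.05)
})

test_that("a species with zero suitability is never recorded", {
  env <- small_env()
  pool <- generate_species_pool(2, niche_config(
    predictors = list(T = list(opt = c(15, 15), breadth = c(4, 4)))),
    seed = 1)
  pool$opt_T[2] <- 500   # suitability underflows to zero on the grid
  eff <- effort_model(env$grid, "uniform", seed = 1)
  occ <- sample_occurrences(pool, env, eff, 2000, seed = 2)
  expect_false(pool$species_id[2] %in% occ$scientificName)
  expect_true(pool$species_id[1] %in% occ$scientificName)
})

test_that("uniform effort yields uniform per-cell event counts", {
  g <- grid_spec(10, 8, lat_min = 0, lon_min = 0)
  env <- generate_environment(g, env_config(n_land_cols = 0,
                                            n_shelf_cols = 0,
                                            brackish_cells = 0), seed = 4)
  ## one ubiquitous species so records mirror sampling events exactly
  pool <- generate_species_pool(1, niche_config(
    predictors = list(T = list(opt = c(15, 15), breadth = c(1e6, 1e6))),
    max_prob = c(1, 1)), seed = 1)
  eff <- effort_model(g, "uniform", seed = 1)
  occ <- sample_occurrences(pool, env, eff, 10000, seed = 3,
                            p_fossil = 0, p_preserved = 0, p_bad_year = 0)
  cells <- latlon_to_cell(g, occ$decimalLatitude, occ$decimalLongitude)
  counts <- table(factor(paste(cells$lat_idx, cells$lon_idx),
                         levels = paste(rep(1:10, 8),
                                        rep(1:8, each = 10))))
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.01)
})

test_that("record density tracks effort intensity (sampling-bias realism)", {
  env <- small_env()
  g <- env$grid
  pool <- generate_species_pool(1, niche_config(
    predictors = list(T = list(opt = c(15, 15), breadth = c(1e6, 1e6))),
    max_prob = c(1, 1)), seed = 1)
  eff <- effort_model(g, "biased", env = env, seed = 2)
  occ <- sample_occurrences(pool, env, eff, 50000, seed = 3)
  cells <- latlon_to_cell(g, occ$decimalLatitude, occ$decimalLongitude)
  dens <- table(factor(paste(cells$lat_idx, cells$lon_idx),
                       levels = paste(rep(seq_len(g$n_lat), g$n_lon),
                                      rep(seq_len(g$n_lon),
                                          each = g$n_lat))))
  eff_cell <- apply(unclass(eff), c(2, 3), sum)
  rho <- stats::cor(as.vector(dens), as.vector(eff_cell),
                    method = "spearman")
  expect_gte(rho, 0.95)
})

test_that("occurrence sampling is deterministic and rejects zero effort", {
  env <- small_env()
  pool <- suppressWarnings(generate_metabolic_pool(20, 0.32, env,
                                                   seed = 1))
  eff <- effort_model(env$grid, "uniform", env = env, seed = 1)
  o1 <- sample_occurrences(pool, env, eff, 500, seed = 11)
  o2 <- sample_occurrences(pool, env, eff, 500, seed = 11)
  expect_identical(o1, o2)
  bad <- eff
  bad[] <- 0
  expect_error(sample_occurrences(pool, env, bad, 10, seed = 1),
               "zero")
})

test_that("occurrence CSV round-trips through Darwin Core headers", {
  env <- small_env()
  pool <- suppressWarnings(generate_metabolic_pool(10, 0.32, env,
                                                   seed = 1))
  eff <- effort_model(env$grid, "uniform", env = env, seed = 1)
  occ <- sample_occurrences(pool, env, eff, 300, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_occurrences(occ, f)
  back <- read_occurrences(f)
  expect_equal(nrow(back), nrow(occ))
  expect_equal(back$scientificName, occ$scientificName)
  expect_equal(back$depth, occ$depth, tolerance = 1e-9)
  unlink(f)
})
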