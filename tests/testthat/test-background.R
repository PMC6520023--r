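## Helper: gridded presences built directly from a key table.
as_presences <- function(df, g) {
  df <- unique(df)
  df <- df[order(df$species_id, df$month, df$lat_idx, df$lon_idx), ]
  rownames(df) <- NULL
  counts <- table(factor(df$species_id))
  structure(df, grid = g,
            counts = stats::setNames(as.integer(counts), names(counts)),
            class = c("gridded_presences", "data.frame"))
}

test_that("target groups follow the group-specific taxon rules", {
  g <- grid_spec(4, 3, lat_min = 0, lon_min = 0)
  pres <- as_presences(data.frame(
    species_id = c("d1", "d1", "d2", "dino1", "hap1", "chl1"),
    month = c(1, 2, 1, 3, 4, 5),
    lat_idx = c(1, 1, 2, 3, 4, 1),
    lon_idx = c(1, 2, 1, 1, 2, 3),
    stringsAsFactors = FALSE), g)
  gm <- c(d1 = "Bacillariophyceae", d2 = "Bacillariophyceae",
          dino1 = "Dinoflagellata", hap1 = "Haptophyta",
          chl1 = "Chlorophyta")
  tg <- build_target_group(pres, gm, mode = "group-specific")
  ## diatom species: own taxon's pooled cells only
  expect_equal(nrow(tg[["d1"]]), 3)
  ## non-core taxon: pool of all species except diatoms
  expect_equal(nrow(tg[["chl1"]]), 3)   # dino1 + hap1 + chl1 cells
  ## total mode: identical pool for everyone
  tt <- build_target_group(pres, gm, mode = "total")
  expect_identical(tt[["d1"]], tt[["chl1"]])
  expect_equal(nrow(tt[["d1"]]), 6)
  ## unknown taxon falls back to the total pool with a warning
  gm2 <- gm[names(gm) != "chl1"]
  gm2["chl1"] <- NA
  expect_warning(tg2 <- build_target_group(pres, gm2,
                                           mode = "group-specific"),
                 "unknown")
  expect_equal(nrow(tg2[["chl1"]]), 6)
})

test_that("target-group cells carry species multiplicity", {
  g <- grid_spec(4, 3, lat_min = 0, lon_min = 0)
  pres <- as_presences(data.frame(
    species_id = c("a", "b", "c"),
    month = c(1, 1, 1), lat_idx = c(2, 2, 2), lon_idx = c(2, 2, 2),
    stringsAsFactors = FALSE), g)
  tg <- build_target_group(pres, c(a = "x", b = "x", c = "x"),
                           mode = "total")
  expect_equal(nrow(tg[["a"]]), 1)
  expect_equal(tg[["a"]]$weight, 3L)
})

test_that("nine equal-width bins per axis give exactly 81 strata", {
  g <- grid_spec(10, 10, lat_min = 0, lon_min = 0)
  dims <- c(12, 10, 10)
  set.seed(7)
  env <- env_clim(g, list(T = array(runif(prod(dims), 0, 27), dims),
                          MLD = array(runif(prod(dims), 10, 100), dims),
                          S = array(35, dims),
                          bathymetry = array(4000, dims)))
  group <- data.frame(month = sample(12, 400, TRUE),
                      lat_idx = sample(10, 400, TRUE),
                      lon_idx = sample(10, 400, TRUE), weight = 1L)
  st <- stratify(group, env, n_bins = 9)
  expect_equal(st$n_strata, 81L)
  expect_equal(length(st$t_edges), 10L)
  expect_true(all(st$cells$stratum >= 1 & st$cells$stratum <= 81))
})

test_that("bin edges span [min, max] with the maximum edge inclusive", {
  g <- grid_spec(9, 2, lat_min = 0, lon_min = 0)
  dims <- c(12, 9, 2)
  tvals <- array(0, dims)
  tvals[1, , 1] <- seq(0, 24, by = 3)   # 0,3,...,24
  tvals[1, 9, 2] <- 27                  # the maximum
  env <- env_clim(g, list(T = tvals, MLD = array(50, dims)))
  group <- data.frame(month = 1,
                      lat_idx = c(1:9, 9), lon_idx = c(rep(1, 9), 2))
  st <- suppressWarnings(stratify(group, env, n_bins = 9))  # MLD constant
  expect_equal(st$t_edges, seq(0, 27, by = 3))
  expect_equal(st$cells$t_bin[st$cells$lon_idx == 2], 9L)
  expect_equal(st$cells$t_bin[st$cells$lat_idx == 1 &
                                st$cells$lon_idx == 1], 1L)
})

test_that("a degenerate axis collapses to a single bin", {
  g <- grid_spec(5, 2, lat_min = 0, lon_min = 0)
  dims <- c(12, 5, 2)
  set.seed(1)
  env <- env_clim(g, list(T = array(runif(prod(dims), 0, 20), dims),
                          MLD = array(42, dims)))
  group <- data.frame(month = sample(12, 50, TRUE),
                      lat_idx = sample(5, 50, TRUE),
                      lon_idx = sample(2, 50, TRUE))
  expect_warning(st <- stratify(group, env), "degenerate")
  expect_equal(st$n_strata, 9L)
})

test_that("background size is ten times the presence count when cells
           allow", {
  env <- small_env()
  g <- env$grid
  set.seed(12)
  ## focal species with exactly 24 presences inside a big target group
  all_cells <- expand.grid(month = 1:12, lat_idx = 1:20, lon_idx = 1:7)
  pick <- all_cells[sample(nrow(all_cells), 500), ]
  pres <- as_presences(rbind(
    data.frame(species_id = "focal", pick[1:24, ]),
    data.frame(species_id = "other", pick[25:500, ])), g)
  tg <- build_target_group(pres, c(focal = "x", other = "x"), "total")
  st <- stratify(tg[["focal"]], env)
  bg <- sample_background("focal", pres, st, ratio = 10, seed = 3)
  expect_equal(nrow(bg), 240L)
  expect_equal(attr(bg, "target_size"), 240L)
  ## no background key coincides with a presence key of the species
  own <- pres[pres$species_id == "focal", ]
  expect_equal(nrow(merge(bg, own,
                          by = c("month", "lat_idx", "lon_idx"))), 0L)
  ## deterministic under the seed
  bg2 <- sample_background("focal", pres, st, ratio = 10, seed = 3)
  expect_identical(bg, bg2)
})

test_that("stratum quotas are proportional with largest-remainder
           rounding", {
  w <- c(50, 30, 20)
  q <- phytosdm:::largest_remainder(w, 10)
  expect_equal(q, c(5L, 3L, 2L))
  expect_equal(sum(phytosdm:::largest_remainder(c(1, 1, 1), 10)), 10L)
  expect_equal(phytosdm:::largest_remainder(c(0, 5), 7), c(0L, 7L))
  ## empty stratum receives zero
  expect_equal(phytosdm:::largest_remainder(c(3, 0, 7), 10)[2], 0L)
})

test_that("exhausted strata redistribute their deficit", {
  g <- grid_spec(4, 3, lat_min = 0, lon_min = 0)
  dims <- c(12, 4, 3)
  tvals <- array(rep(c(5, 25), each = 6), dims)  # two T levels
  env <- env_clim(g, list(T = tvals, MLD = array(50, dims)))
  ## tiny group: 3 cells in the cold stratum, many in the warm one
  cells <- expand.grid(month = 1:12, lat_idx = 1:4, lon_idx = 1:3)
  tcell <- env_matchup(env, cells, "T")$T
  group <- rbind(cells[tcell == 5, ][1:3, ], cells[tcell == 25, ][1:60, ])
  group$weight <- 1L
  pres <- as_presences(data.frame(species_id = "f",
                                  cells[tcell == 25, ][61:66, ]), g)
  st <- suppressWarnings(stratify(group, env))
  bg <- suppressWarnings(sample_background("f", pres, st, ratio = 10,
                                           seed = 1))
  ## target 60; cold stratum holds only 3 cells, the rest must come from
  ## the warm stratum
  expect_equal(nrow(bg), 60L)
  expect_lte(sum(bg$stratum == bg$stratum[which.min(bg$stratum)]), 60L)
})

test_that("background density mirrors target-group (effort) density
           across cells", {
  env <- small_env()
  g <- env$grid
  ## synthetic target group: sampling events per monthly cell drawn with
  ## strongly heterogeneous, basin-biased intensity; the group's gridded
  ## cell density across space then mirrors that effort
  set.seed(22)
  lam <- matrix(exp(stats::rnorm(g$n_lat * g$n_lon, 0, 1.2)),
                g$n_lat, g$n_lon)
  lam[, 1:2] <- lam[, 1:2] * 8            # heavily sampled basin
  lam[is.na(env_field(env, "T")[1, , ])] <- 0
  lam <- lam * 1.2 / mean(lam[lam > 0])   # ~1.2 events per monthly cell
  rows <- list()
  for (i in seq_len(g$n_lat)) for (j in seq_len(g$n_lon)) {
    if (lam[i, j] == 0) next
    for (m in 1:12) {
      k <- stats::rpois(1, lam[i, j])
      if (k > 0)
        rows[[length(rows) + 1]] <- data.frame(
          species_id = paste0("g", seq_len(k)), month = m,
          lat_idx = i, lon_idx = j, stringsAsFactors = FALSE)
    }
  }
  group_df <- do.call(rbind, rows)
  ocean_cells <- which(lam > 0, arr.ind = TRUE)
  focal_cells <- ocean_cells[sample(nrow(ocean_cells), 100, TRUE), ]
  focal_df <- unique(data.frame(species_id = "focal",
                                month = sample(12, 100, TRUE),
                                lat_idx = focal_cells[, 1],
                                lon_idx = focal_cells[, 2],
                                stringsAsFactors = FALSE))
  pres <- as_presences(rbind(focal_df, group_df), g)
  gm <- stats::setNames(rep("x", length(unique(pres$species_id))),
                        unique(pres$species_id))
  tg <- build_target_group(pres, gm, "total")
  st <- stratify(tg[["focal"]], env)
  bg <- suppressWarnings(sample_background("focal", pres, st, ratio = 10,
                                           seed = 23))
  cell_id <- function(d) paste(d$lat_idx, d$lon_idx)
  lv <- cell_id(expand.grid(lat_idx = 1:g$n_lat, lon_idx = 1:g$n_lon))
  bg_dens <- table(factor(cell_id(bg), levels = lv))
  tg_dens <- table(factor(cell_id(tg[["focal"]]), levels = lv))
  keep <- tg_dens > 0
  rho <- stats::cor(as.vector(bg_dens[keep]), as.vector(tg_dens[keep]),
                    method = "spearman")
  expect_gte(rho, 0.9)
})
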