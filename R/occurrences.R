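#' Spatial sampling-effort model
#'
#' Presence-only archives are strongly biased in space: in global
#' phytoplankton compilations about half of all records come from a single
#' well-sampled basin.  The effort model captures this as a per-cell,
#' per-month relative sampling intensity.  The default `"biased"` type
#' concentrates `basin_frac` of the total intensity in a contiguous block of
#' longitude columns (a "north Atlantic" analogue spanning all latitudes,
#' so effort is uneven in space but balanced along the temperature
#' gradient); heterogeneity within and outside the basin comes from a
#' seeded gamma field.
#'
#' @param spec A [grid_spec()].
#' @param type `"biased"` or `"uniform"`.
#' @param basin_frac Fraction of total intensity placed in the basin
#'   (default 0.49).
#' @param basin_lon_frac Fraction of longitude columns forming the basin.
#' @param env Optional [env_clim()]; cells that are `NA` in its temperature
#'   field get zero effort.
#' @param seed Integer seed.
#' @return An object of class `effort_model`: a `(12, n_lat, n_lon)` array
#'   of nonnegative intensities summing to 1, with the basin columns stored
#'   in `attr(, "basin_cols")`.
#' @export
effort_model <- function(spec, type = c("biased", "uniform"),
                         basin_frac = 0.49, basin_lon_frac = 0.25,
                         env = NULL, seed = 1) {
  stopifnot(is_grid_spec(spec))
  type <- match.arg(type)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  dims <- c(12L, spec$n_lat, spec$n_lon)
  eff <- if (type == "uniform") array(1, dim = dims)
  else array(stats::rgamma(prod(dims), shape = 2, rate = 2), dim = dims)
  if (!is.null(env)) {           # land first, so basin shares are exact
    stopifnot(same_grid(spec, env$grid))
    eff[is.na(env_field(env, "T"))] <- 0
  }
  basin_cols <- integer(0)
  if (type == "biased") {
    stopifnot(basin_frac > 0, basin_frac < 1,
              basin_lon_frac > 0, basin_lon_frac < 1)
    n_basin <- max(1L, round(basin_lon_frac * spec$n_lon))
    basin_cols <- seq_len(n_basin)
    inside <- sum(eff[, , basin_cols])
    outside <- sum(eff[, , -basin_cols, drop = FALSE])
    if (inside == 0 || outside == 0)
      stop("effort_model: basin or open sector has zero samplable cells")
    eff[, , basin_cols] <- eff[, , basin_cols] * basin_frac / inside
    eff[, , -basin_cols] <- eff[, , -basin_cols] *
      (1 - basin_frac) / outside
  }
  if (sum(eff) == 0) stop("effort_model: all intensities are zero")
  eff <- eff / sum(eff)
  structure(eff, basin_cols = basin_cols, class = "effort_model")
}

#' Sample biased presence-only occurrence records
#'
#' Draws `n_samples` sampling events (monthly 1-degree cells) with
#' probability proportional to the effort model, then records each species
#' at each event with probability equal to its true suitability there.
#' Output rows carry Darwin Core style fields (coordinates jittered within
#' the cell, a sampling depth, a collection date, and a basis-of-record
#' flag) so the record-cleaning rules downstream are exercisable.  Small
#' configurable fractions of contaminated rows (fossil/preserved basis,
#' out-of-window years, below-mixed-layer depths, missing depths) are
#' injected to mirror the noise in real archives.
#'
#' @param pool A `species_pool`.
#' @param env An [env_clim()] on the same grid.
#' @param effort An [effort_model()] on the same grid.
#' @param n_samples Number of sampling events (> 0).
#' @param seed Integer seed.
#' @param year_window Inclusive year range for valid collection years.
#' @param year_mean,year_sd Gaussian draw for collection year, clipped to
#'   `year_window`.
#' @param p_fossil,p_preserved Fractions of records flagged as fossil or
#'   preserved specimens.
#' @param p_bad_year Fraction of records given a year outside 1800-2015.
#' @param p_deep Fraction of records placed below the local mixed layer.
#' @param p_depth_missing Fraction of records with missing depth.
#' @return A data frame of class `occurrence_table` with columns
#'   `scientificName`, `decimalLatitude`, `decimalLongitude`, `depth`,
#'   `year`, `month`, `day`, `basisOfRecord`.
#' @export
sample_occurrences <- function(pool, env, effort, n_samples, seed = 1,
                               year_window = c(1950, 2000),
                               year_mean = 1984, year_sd = 17,
                               p_fossil = 0.01, p_preserved = 0.01,
                               p_bad_year = 0.005, p_deep = 0.03,
                               p_depth_missing = 0.15) {
  stopifnot(inherits(pool, "species_pool"), inherits(env, "env_clim"),
            inherits(effort, "effort_model"), n_samples >= 1)
  if (!all(dim(effort) == c(12L, env$grid$n_lat, env$grid$n_lon)))
    stop("sample_occurrences: effort and climatology grids differ")
  if (sum(effort) <= 0) stop("sample_occurrences: effort is all zero")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  g <- env$grid

  ## sampling events ~ multinomial over monthly cells
  p <- as.vector(effort) / sum(effort)
  counts <- as.vector(stats::rmultinom(1, n_samples, p))
  ev_idx <- rep(which(counts > 0), counts[counts > 0])
  ai <- arrayInd(ev_idx, dim(effort))
  ev <- data.frame(month = ai[, 1], lat_idx = ai[, 2], lon_idx = ai[, 3])
  n_ev <- nrow(ev)

  ## detection: one Bernoulli per (event, species) at the true suitability
  suit <- pool_suitability_at(pool, env, ev_idx)
  suit[is.na(suit)] <- 0
  hits <- which(matrix(stats::runif(length(suit)), nrow(suit)) < suit,
                arr.ind = TRUE)
  if (nrow(hits) == 0) {
    out <- data.frame(scientificName = character(0),
                      decimalLatitude = numeric(0),
                      decimalLongitude = numeric(0), depth = numeric(0),
                      year = integer(0), month = integer(0),
                      day = integer(0), basisOfRecord = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("occurrence_table", "data.frame")
    return(out)
  }
  e <- hits[, 1]; s <- hits[, 2]
  n <- length(e)

  jit_lat <- stats::runif(n_ev); jit_lon <- stats::runif(n_ev)
  lat <- g$lat_min + ev$lat_idx[e] - 1 + jit_lat[e]
  lon <- g$lon_min + ev$lon_idx[e] - 1 + jit_lon[e]

  mld_ev <- env_field(env, "MLD")[ev_idx]
  depth <- pmin(abs(stats::rnorm(n, 5.4, 7)), pmax(mld_ev[e] - 1, 0.5))
  deep <- stats::runif(n) < p_deep
  depth[deep] <- mld_ev[e][deep] + stats::runif(sum(deep), 10, 80)
  depth[stats::runif(n) < p_depth_missing] <- NA_real_

  year <- as.integer(round(stats::rnorm(n, year_mean, year_sd)))
  year <- pmin(pmax(year, year_window[1]), year_window[2])
  bad <- stats::runif(n) < p_bad_year
  year[bad] <- sample(c(1750L, 1790L, 2016L, 2020L), sum(bad),
                      replace = TRUE)

  basis <- rep("HumanObservation", n)
  u <- stats::runif(n)
  basis[u < p_fossil] <- "FossilSpecimen"
  basis[u >= p_fossil & u < p_fossil + p_preserved] <- "PreservedSpecimen"

  out <- data.frame(
    scientificName = pool$species_id[s],
    decimalLatitude = lat,
    decimalLongitude = lon,
    depth = depth,
    year = year,
    month = ev$month[e],
    day = sample(28L, n, replace = TRUE),
    basisOfRecord = basis,
    stringsAsFactors = FALSE
  )
  class(out) <- c("occurrence_table", "data.frame")
  out
}

#' Read and write occurrence tables as Darwin Core style CSV
#'
#' @param records An `occurrence_table` data frame.
#' @param path File path.
#' @return `write_occurrences` returns `path` invisibly; `read_occurrences`
#'   returns an `occurrence_table`.
#' @export
write_occurrences <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  req <- c("scientificName", "decimalLatitude", "decimalLongitude",
           "depth", "year", "month", "day", "basisOfRecord")
  miss <- setdiff(req, names(out))
  if (length(miss))
    stop("read_occurrences: missing columns: ",
         paste(miss, collapse = ", "))
  class(out) <- c("occurrence_table", "data.frame")
  out
}
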