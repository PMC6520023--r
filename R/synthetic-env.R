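#' Configuration for the virtual environment generator
#'
#' The simulator produces an idealised two-hemisphere ocean on an arbitrary
#' grid: the grid's central row plays the role of the equator and the top and
#' bottom rows play the role of the poles, so the configured temperature span
#' is always resolved regardless of grid size.  The statistical structure --
#' a poleward temperature decline, mid-latitude seasonal amplitude exceeding
#' the tropical amplitude, winter-deep mixed layers, nutrient concentrations
#' anticorrelated with temperature, and a consistent land/shelf/brackish
#' mask -- is what the downstream modelling pipeline assumes of real
#' climatologies; no circulation or biogeochemistry is emulated.
#'
#' @param t_range Closed bounds (degrees C) for sea surface temperature;
#'   generated values never leave this interval.
#' @param t_seasonal Length-2 vector: seasonal amplitude (degrees C) at the
#'   equator row and at mid-latitudes; the mid-latitude value must be the
#'   larger so seasonality peaks away from the tropics.
#' @param t_noise_sd Standard deviation of the static spatial temperature
#'   noise (degrees C).
#' @param nutrient_t_cor Strength in `[0, 1]` of the nitrate-temperature
#'   anticorrelation (1 = deterministic function of temperature).
#' @param mld_range Depth range (m) of the annual-mean mixed layer from
#'   equator to mid-latitudes.
#' @param mld_seasonal Relative seasonal amplitude of the mixed layer (< 1).
#' @param par_range Annual-mean photosynthetically active radiation
#'   (umol m-2 s-1) at the poles and the equator.
#' @param n_land_cols Number of longitude columns masked as land (all
#'   variables `NA` in all months).
#' @param n_shelf_cols Number of longitude columns given shelf bathymetry
#'   (< 200 m); used to exercise the open-ocean mask.
#' @param brackish_cells Number of cells given surface salinity below 20.
#' @return A list of class `env_config`.
#' @export
env_config <- function(t_range = c(-1.8, 32),
                       t_seasonal = c(1, 4),
                       t_noise_sd = 0.3,
                       nutrient_t_cor = 0.9,
                       mld_range = c(20, 140),
                       mld_seasonal = 0.6,
                       par_range = c(8, 55),
                       n_land_cols = 1,
                       n_shelf_cols = 1,
                       brackish_cells = 4) {
  stopifnot(length(t_range) == 2, t_range[1] < t_range[2],
            length(t_seasonal) == 2, all(t_seasonal >= 0),
            t_seasonal[2] >= t_seasonal[1],
            nutrient_t_cor >= 0, nutrient_t_cor <= 1,
            mld_range[1] > 0, mld_range[2] >= mld_range[1],
            mld_seasonal >= 0, mld_seasonal < 1)
  structure(as.list(environment()), class = "env_config")
}

#' Generate a virtual monthly climatology
#'
#' Deterministic given `(spec, config, seed)`.  Eleven variables are
#' produced: `T`, `S`, `NO3`, `PO4`, `SiOH4`, `MLD`, `PAR`, `Chl`, `wind`,
#' `pCO2` and `bathymetry`, each on the monthly 1-degree grid.  Temperature
#' decreases from the grid's central row towards its edges with a seasonal
#' cycle (antiphase between hemispheres) whose amplitude peaks at
#' mid-latitudes; values that noise or seasonality would push outside
#' `config$t_range` are clipped with a warning.  Nutrients decline with
#' temperature, phosphate tracks nitrate near the 16:1 ratio, and the
#' land/shelf/brackish mask is identical in every month.
#'
#' @param spec A [grid_spec()].
#' @param config An [env_config()].
#' @param seed Integer seed.
#' @return An [env_clim()] object.
#' @export
generate_environment <- function(spec, config = env_config(), seed = 1) {
  stopifnot(is_grid_spec(spec), inherits(config, "env_config"))
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  nla <- spec$n_lat; nlo <- spec$n_lon
  dims <- c(12L, nla, nlo)
  ## pseudo-latitude: 0 at the central row, 1 at the outermost rows;
  ## sign separates the two model hemispheres (antiphase seasons)
  rows <- seq_len(nla)
  centre <- (nla + 1) / 2
  phi <- abs(rows - centre) / (nla - centre)
  hemi <- ifelse(rows >= centre, 1, -1)

  amp <- config$t_seasonal[1] +
    (config$t_seasonal[2] - config$t_seasonal[1]) * sin(pi * phi)^2
  t_lo <- config$t_range[1]; t_hi <- config$t_range[2]
  lon_amp <- 0.8
  margin <- lon_amp + 4 * config$t_noise_sd
  t_mean <- (t_hi - amp[which.min(phi)] - margin) -
    ((t_hi - amp[which.min(phi)]) - (t_lo + amp[which.max(phi)]) -
       2 * margin) * phi

  season <- function(m, peak) cos(2 * pi * (m - peak) / 12)
  cell_noise <- function(sd) {
    n <- matrix(stats::rnorm(nla * nlo, 0, sd), nla, nlo)
    aperm(array(n, dim = c(nla, nlo, 12)), c(3, 1, 2))
  }
  lon_wave <- aperm(array(matrix(sin(2 * pi * seq_len(nlo) / nlo),
                                 nla, nlo, byrow = TRUE),
                          dim = c(nla, nlo, 12)), c(3, 1, 2))
  expand_lat <- function(v) {   # per-row vector -> (12, nla, nlo)
    aperm(array(matrix(v, nla, nlo), dim = c(nla, nlo, 12)), c(3, 1, 2))
  }
  expand_month_lat <- function(m) {  # (12, nla) matrix -> array
    array(m, dim = dims)
  }

  seas_T <- outer(1:12, rows, function(m, r)
    hemi[r] * amp[r] * season(m, 8))
  Tfield <- expand_lat(t_mean) + expand_month_lat(seas_T) +
    lon_amp * lon_wave + cell_noise(config$t_noise_sd)
  n_clip <- sum(Tfield < t_lo | Tfield > t_hi, na.rm = TRUE)
  if (n_clip > 0) {
    warning(sprintf(
      "generate_environment: %d temperature values clipped to [%g, %g]",
      n_clip, t_lo, t_hi))
    Tfield <- pmin(pmax(Tfield, t_lo), t_hi)
  }

  Sfield <- 35 + 1.2 * lon_wave + cell_noise(0.25)

  ## nitrate: cold water is nutrient rich; mixing term adds weak seasonality
  t_rel <- (t_hi - Tfield) / (t_hi - t_lo)
  rho <- config$nutrient_t_cor
  no3 <- 30 * (rho * t_rel^1.6 +
                 (1 - rho) * abs(cell_noise(0.5))) +
    expand_month_lat(outer(1:12, rows, function(m, r)
      1.5 * phi[r] * pmax(hemi[r] * season(m, 2), 0)))
  no3 <- pmax(no3, 0)

  po4 <- no3 / 16 + 0.12 * lon_wave^2 + cell_noise(0.04)
  po4 <- pmax(po4, 0)

  ## silicate tracks nitrate through an independent, static Si:N ratio
  ## field, so the ratio predictor is decoupled from temperature
  sioh4 <- no3 * exp(cell_noise(0.5))
  sioh4 <- pmax(sioh4, 0)

  ## mixed layer: weak latitudinal deepening, strong independent spatial
  ## structure (storm tracks, gyres), winter-deep seasonality
  mld_base <- config$mld_range[1] +
    (config$mld_range[2] - config$mld_range[1]) * (0.25 + 0.75 * phi)
  seas_M <- outer(1:12, rows, function(m, r)
    1 + config$mld_seasonal * hemi[r] * season(m, 2) * (0.3 + 0.7 * phi[r]))
  mld <- expand_lat(mld_base) * expand_month_lat(seas_M) *
    exp(cell_noise(0.55))
  mld <- pmax(mld, 1)

  par_mean <- config$par_range[2] -
    (config$par_range[2] - config$par_range[1]) * phi^1.2
  seas_P <- outer(1:12, rows, function(m, r)
    1 + 0.35 * phi[r] * hemi[r] * season(m, 7))
  par <- expand_lat(par_mean) * expand_month_lat(seas_P) +
    cell_noise(1.0)
  par <- pmax(par, 0.5)

  ## chlorophyll: mid-latitude bloom seasonality on patchy background,
  ## only weakly nutrient-linked
  bloom <- outer(1:12, rows, function(m, r)
    1 + 1.5 * sin(pi * phi[r])^2 * (1 + 0.8 * hemi[r] * season(m, 4)))
  chl <- 0.15 * exp(cell_noise(0.5)) * expand_month_lat(bloom) *
    (1 + 0.15 * no3 / 30)
  chl <- pmax(chl, 0.01)

  wind <- 4 + 6 * expand_lat(sin(pi * phi)^2) +
    expand_month_lat(outer(1:12, rows, function(m, r)
      1.2 * hemi[r] * season(m, 1) * phi[r])) + cell_noise(0.4)
  wind <- pmax(wind, 0)

  pco2 <- 360 + 0.9 * (Tfield - mean(Tfield)) + cell_noise(3)

  bathy_mat <- matrix(4000 + stats::rnorm(nla * nlo, 0, 500), nla, nlo)
  shelf_cols <- integer(0)
  if (config$n_shelf_cols > 0)
    shelf_cols <- seq_len(config$n_shelf_cols)
  if (length(shelf_cols))
    bathy_mat[, shelf_cols] <- stats::runif(nla * length(shelf_cols), 50, 180)
  bathy <- aperm(array(bathy_mat, dim = c(nla, nlo, 12)), c(3, 1, 2))

  ## brackish marginal-sea cells (low salinity, open-ocean mask fodder)
  if (config$brackish_cells > 0) {
    free_cols <- setdiff(seq_len(nlo), shelf_cols)
    bc <- cbind(sample(seq_len(nla), config$brackish_cells, replace = TRUE),
                sample(free_cols, config$brackish_cells, replace = TRUE))
    for (i in seq_len(nrow(bc)))
      Sfield[, bc[i, 1], bc[i, 2]] <- stats::runif(12, 10, 18)
  }

  fields <- list(T = Tfield, S = Sfield, NO3 = no3, PO4 = po4,
                 SiOH4 = sioh4, MLD = mld, PAR = par, Chl = chl,
                 wind = wind, pCO2 = pco2, bathymetry = bathy)

  ## land mask: whole longitude columns, identical across months and fields
  if (config$n_land_cols > 0) {
    land_cols <- nlo - seq_len(config$n_land_cols) + 1
    for (nm in names(fields)) fields[[nm]][, , land_cols] <- NA_real_
  }

  env_clim(spec, fields)
}
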