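## Shared fixtures, built once per test run.  All synthetic: nothing is
## read from disk.

fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_cache))
    assign(key, expr, envir = fixture_cache)
  get(key, envir = fixture_cache)
}

## Small virtual world: 20 x 8 one-degree cells, all variables derived.
small_env <- function() memo("small_env", {
  g <- grid_spec(20, 8, lat_min = -10, lon_min = 0)
  derive_predictors(generate_environment(g, seed = 42))
})

small_grid <- function() small_env()$grid

## Hand-built climatology with fully controlled values on a 4 x 3 grid;
## convenient for exact filter/mask arithmetic.
toy_env <- function(t_vals = NULL) {
  g <- grid_spec(4, 3, lat_min = 0, lon_min = 0)
  dims <- c(12L, 4L, 3L)
  const <- function(x) array(x, dim = dims)
  Tf <- if (is.null(t_vals)) const(15) else t_vals
  env_clim(g, list(
    T = Tf, S = const(35), NO3 = const(8), PO4 = const(0.5),
    SiOH4 = const(4), MLD = const(50), PAR = const(30),
    Chl = const(0.2), wind = const(6), pCO2 = const(380),
    bathymetry = const(3000)))
}

## Occurrence rows with sensible defaults; override any column.
make_records <- function(n = 1, ...) {
  out <- data.frame(
    scientificName = rep("spA", n),
    decimalLatitude = rep(1.5, n),
    decimalLongitude = rep(1.5, n),
    depth = rep(5, n),
    year = rep(1980L, n),
    month = rep(6L, n),
    day = rep(10L, n),
    basisOfRecord = rep("HumanObservation", n),
    stringsAsFactors = FALSE
  )
  args <- list(...)
  for (nm in names(args)) out[[nm]] <- args[[nm]]
  class(out) <- c("occurrence_table", "data.frame")
  out
}

## Fabricated ensemble projection from a values array.
make_ensemble <- function(values, id = "spX", n_retained = 1L) {
  structure(list(species_id = id, values = values,
                 n_retained = n_retained),
            class = "ensemble_projection")
}

## Presence/background training table for a species whose occurrence
## probability is a Gaussian function of temperature, plus junk columns.
thermal_training_data <- function(n_pres = 60, n_bg = 600, opt = 20,
                                  breadth = 4, seed = 99) {
  set.seed(seed)
  t_bg <- runif(n_bg, -2, 32)
  t_pres <- numeric(0)
  while (length(t_pres) < n_pres) {
    cand <- runif(n_pres * 4, -2, 32)
    keep <- runif(length(cand)) < exp(-(cand - opt)^2 / (2 * breadth^2))
    t_pres <- c(t_pres, cand[keep])
  }
  t_pres <- t_pres[seq_len(n_pres)]
  d <- data.frame(label = rep(c(1, 0), c(n_pres, n_bg)),
                  T = c(t_pres, t_bg))
  d$junk1 <- rnorm(nrow(d))
  d$junk2 <- rnorm(nrow(d))
  d$junk3 <- runif(nrow(d))
  d
}
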