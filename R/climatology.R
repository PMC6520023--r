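#' Monthly gridded environmental climatologies
#'
#' An `env_clim` object holds one array per environmental variable, each
#' dimensioned `(12, n_lat, n_lon)` over a shared [grid_spec()].  Missing
#' values (`NA`) mark land or unobserved cells and must be consistent within
#' a variable across uses; different variables may have different coverage.
#'
#' @param spec A [grid_spec()].
#' @param fields A named list of numeric arrays, each with dimensions
#'   `c(12, spec$n_lat, spec$n_lon)`.
#' @return An object of class `env_clim`.
#' @export
env_clim <- function(spec, fields) {
  stopifnot(is_grid_spec(spec), is.list(fields), length(fields) > 0)
  if (is.null(names(fields)) || any(!nzchar(names(fields))))
    stop("env_clim: all fields must be named")
  dims <- c(12L, spec$n_lat, spec$n_lon)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (!is.numeric(f) || !identical(dim(f), dims))
      stop(sprintf("env_clim: field '%s' must be a numeric array (12, %d, %d)",
                   nm, spec$n_lat, spec$n_lon))
  }
  structure(list(grid = spec, fields = fields), class = "env_clim")
}

#' @export
print.env_clim <- function(x, ...) {
  cat(sprintf("<env_clim> %d x %d grid, %d variables:\n",
              x$grid$n_lat, x$grid$n_lon, length(x$fields)))
  cat(" ", paste(names(x$fields), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname env_clim
#' @param env An `env_clim` object.
#' @param var A variable name present in `env`.
#' @export
env_field <- function(env, var) {
  stopifnot(inherits(env, "env_clim"))
  if (!var %in% names(env$fields))
    stop(sprintf("env_field: no variable '%s' in climatology", var))
  env$fields[[var]]
}

#' @rdname env_clim
#' @export
env_vars <- function(env) names(env$fields)

#' Look up climatology values at monthly cells
#'
#' Vectorised matchup of environmental values at `(month, lat_idx, lon_idx)`
#' keys, the unit at which presences, backgrounds and projections live.
#'
#' @param env An [env_clim()] object.
#' @param keys A data frame with columns `month`, `lat_idx`, `lon_idx`.
#' @param vars Character vector of variable names (default: all).
#' @return A data frame with one column per variable, rows aligned to `keys`.
#' @export
env_matchup <- function(env, keys, vars = env_vars(env)) {
  stopifnot(inherits(env, "env_clim"))
  req <- c("month", "lat_idx", "lon_idx")
  if (!all(req %in% names(keys)))
    stop("env_matchup: keys must have columns month, lat_idx, lon_idx")
  idx <- cellmonth_index(env$grid, keys$month, keys$lat_idx, keys$lon_idx)
  out <- lapply(vars, function(v) env$fields[[v]][idx])
  names(out) <- vars
  as.data.frame(out, optional = TRUE)
}

#' Open-ocean cell mask
#'
#' Cells count as open ocean when bathymetry is at least `min_depth` metres
#' and surface salinity is at least `min_salinity` in every month where
#' salinity is defined.  Marginal shallow or brackish seas are excluded from
#' the analyses this way.
#'
#' @param env An [env_clim()] with `bathymetry` and `S` fields.
#' @param min_depth Minimum bottom depth in metres (default 200).
#' @param min_salinity Minimum surface salinity (default 20).
#' @return A logical matrix `(n_lat, n_lon)`; `NA`-bathymetry cells are
#'   `FALSE`.
#' @export
open_ocean_cells <- function(env, min_depth = 200, min_salinity = 20) {
  bathy <- env_field(env, "bathymetry")[1, , ]
  sal <- env_field(env, "S")
  sal_min <- apply(sal, c(2, 3), function(v)
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
  ok <- !is.na(bathy) & bathy >= min_depth &
    !is.na(sal_min) & sal_min >= min_salinity
  ok
}

#' Read and write climatologies as long-format CSV
#'
#' The on-disk format is a plain long-format CSV with columns
#' `variable, month, lat_idx, lon_idx, value` (missing cells omitted),
#' preceded by a single comment line carrying the grid specification as
#' JSON.  It round-trips exactly and is readable by every downstream module.
#'
#' @param env An [env_clim()] object.
#' @param path File path.
#' @return `write_climatology` returns `path` invisibly; `read_climatology`
#'   returns an [env_clim()].
#' @export
write_climatology <- function(env, path) {
  stopifnot(inherits(env, "env_clim"))
  g <- env$grid
  hdr <- sprintf("# grid %s", jsonlite::toJSON(
    list(n_lat = g$n_lat, n_lon = g$n_lon,
         lat_min = g$lat_min, lon_min = g$lon_min),
    auto_unbox = TRUE, digits = NA))
  rows <- lapply(names(env$fields), function(v) {
    a <- env$fields[[v]]
    keep <- which(!is.na(a))
    ai <- arrayInd(keep, dim(a))
    data.frame(variable = v, month = ai[, 1], lat_idx = ai[, 2],
               lon_idx = ai[, 3], value = a[keep])
  })
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_climatology
#' @export
read_climatology <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, "# grid "))
    stop("read_climatology: missing grid header line")
  g <- jsonlite::fromJSON(sub("^# grid ", "", hdr))
  spec <- grid_spec(g$n_lat, g$n_lon, g$lat_min, g$lon_min)
  tab <- utils::read.csv(path, comment.char = "#")
  fields <- lapply(split(tab, tab$variable), function(d) {
    a <- array(NA_real_, dim = c(12L, spec$n_lat, spec$n_lon))
    a[cbind(d$month, d$lat_idx, d$lon_idx)] <- d$value
    a
  })
  env_clim(spec, fields)
}
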