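#' Define a monthly 1-degree analysis grid
#'
#' All gridded objects in the package (climatologies, presences, projections,
#' diversity maps) share a common grid: `n_lat` x `n_lon` cells of
#' 1 degree x 1 degree, resolved over the 12 climatological months.  Cells are
#' half-open intervals `[lat, lat + 1) x [lon, lon + 1)`; a record is assigned
#' to a cell by the floor of its coordinates and cell centres sit at +0.5
#' degrees.  This convention bins each record into exactly one cell.
#'
#' @param n_lat Number of 1-degree latitude cells (at least 2).
#' @param n_lon Number of 1-degree longitude cells (at least 2).
#' @param lat_min Latitude (degrees) of the southern edge of the grid.
#' @param lon_min Longitude (degrees) of the western edge of the grid.
#' @return An object of class `grid_spec` with fields `n_lat`, `n_lon`,
#'   `lat_min`, `lon_min` and `months` (the integers 1-12).
#' @examples
#' g <- grid_spec(20, 10, lat_min = -10, lon_min = 0)
#' cell_centers(g)[1, ]
#' @export
grid_spec <- function(n_lat, n_lon, lat_min = 0, lon_min = 0) {
  n_lat <- as.integer(n_lat)
  n_lon <- as.integer(n_lon)
  if (is.na(n_lat) || is.na(n_lon) || n_lat < 2 || n_lon < 2)
    stop("grid_spec: n_lat and n_lon must both be >= 2")
  if (!is.finite(lat_min) || !is.finite(lon_min))
    stop("grid_spec: lat_min and lon_min must be finite")
  if (lat_min < -90 || lat_min + n_lat > 90)
    stop("grid_spec: latitude span must lie within [-90, 90]")
  structure(
    list(n_lat = n_lat, n_lon = n_lon,
         lat_min = lat_min, lon_min = lon_min,
         months = 1:12),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d one-degree cells, 12 months\n",
              x$n_lat, x$n_lon))
  cat(sprintf("  lat [%g, %g), lon [%g, %g)\n",
              x$lat_min, x$lat_min + x$n_lat,
              x$lon_min, x$lon_min + x$n_lon))
  invisible(x)
}

is_grid_spec <- function(x) inherits(x, "grid_spec")

same_grid <- function(a, b) {
  isTRUE(all.equal(a[c("n_lat", "n_lon", "lat_min", "lon_min")],
                   b[c("n_lat", "n_lon", "lat_min", "lon_min")]))
}

#' Cell centres of a grid
#'
#' @param spec A [grid_spec()].
#' @return A data frame with `lat_idx`, `lon_idx`, `lat`, `lon` (centres at
#'   +0.5 degrees), ordered with latitude varying fastest.
#' @export
cell_centers <- function(spec) {
  stopifnot(is_grid_spec(spec))
  data.frame(
    lat_idx = rep(seq_len(spec$n_lat), times = spec$n_lon),
    lon_idx = rep(seq_len(spec$n_lon), each = spec$n_lat),
    lat = spec$lat_min + rep(seq_len(spec$n_lat), times = spec$n_lon) - 0.5,
    lon = spec$lon_min + rep(seq_len(spec$n_lon), each = spec$n_lat) - 0.5
  )
}

#' Assign coordinates to grid cells
#'
#' Coordinates are floored onto the half-open 1-degree cells of `spec`.
#' Points outside the grid get `NA` indices.
#'
#' @param spec A [grid_spec()].
#' @param lat,lon Numeric vectors of coordinates in degrees.
#' @return A data frame with integer columns `lat_idx` and `lon_idx`
#'   (1-based), `NA` where the point falls outside the grid.
#' @export
latlon_to_cell <- function(spec, lat, lon) {
  stopifnot(is_grid_spec(spec))
  li <- floor(lat - spec$lat_min) + 1
  lj <- floor(lon - spec$lon_min) + 1
  li[!is.finite(li) | li < 1 | li > spec$n_lat] <- NA_integer_
  lj[!is.finite(lj) | lj < 1 | lj > spec$n_lon] <- NA_integer_
  data.frame(lat_idx = as.integer(li), lon_idx = as.integer(lj))
}

## Linear index into an array dimensioned (12, n_lat, n_lon).
cellmonth_index <- function(spec, month, lat_idx, lon_idx) {
  month + 12L * ((lat_idx - 1L) + spec$n_lat * (lon_idx - 1L))
}
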