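#' Clean occurrence records
#'
#' Applies the record-exclusion rules in a fixed order, attributing every
#' removed row to the first rule it fails so the filter report is exhaustive
#' and exclusive:
#'
#' 1. `fossil_preserved` -- basis of record is a fossil or preserved
#'    specimen;
#' 2. `year_out_of_range` -- collection year after 2015 or before 1800;
#' 3. `negative_depth` -- depth below zero;
#' 4. `bad_coordinates` -- nonsensible coordinates (non-numeric, `|lat| >
#'    90`, or longitude outside `[-360, 360]`); surviving longitudes are
#'    normalised to `[-180, 180)`;
#' 5. `missing_month` -- no month, so the mixed-layer rule cannot be
#'    applied;
#' 6. `below_mixed_layer` -- recorded depth exceeds the monthly
#'    climatological mixed-layer depth at the record's cell;
#' 7. `depth_missing_no_ml_evidence` -- depth missing and the species has
#'    no other retained record inside the mixed layer.  Missing-depth rows
#'    of species otherwise recorded in the mixed layer are assumed to stem
#'    from the mixed layer and retained.
#'
#' Rows whose cell falls outside the climatology grid, or where the
#' mixed-layer depth is undefined, cannot be tested by rule 6 and are
#' retained here (the open-ocean mask handles off-grid rows).
#'
#' @param records An `occurrence_table`.
#' @param env An [env_clim()] with an `MLD` field.
#' @return A list with `records` (retained rows, longitudes normalised) and
#'   `report` (a [filter_report()]).
#' @export
filter_records <- function(records, env) {
  stopifnot(inherits(env, "env_clim"))
  n <- nrow(records)
  rule <- rep(NA_character_, n)

  basis <- tolower(gsub("[^a-z]", "", tolower(records$basisOfRecord)))
  r1 <- !is.na(basis) & basis %in% c("fossilspecimen", "preservedspecimen")
  rule[is.na(rule) & r1] <- "fossil_preserved"

  yr <- suppressWarnings(as.numeric(records$year))
  r2 <- !is.na(yr) & (yr > 2015 | yr < 1800)
  rule[is.na(rule) & r2] <- "year_out_of_range"

  dp <- suppressWarnings(as.numeric(records$depth))
  r3 <- !is.na(dp) & dp < 0
  rule[is.na(rule) & r3] <- "negative_depth"

  lat <- suppressWarnings(as.numeric(records$decimalLatitude))
  lon <- suppressWarnings(as.numeric(records$decimalLongitude))
  r4 <- is.na(lat) | is.na(lon) | abs(lat) > 90 | lon < -360 | lon > 360
  rule[is.na(rule) & r4] <- "bad_coordinates"
  lon_norm <- ((lon + 180) %% 360) - 180

  mo <- suppressWarnings(as.integer(records$month))
  r5 <- is.na(mo) | mo < 1 | mo > 12
  rule[is.na(rule) & r5] <- "missing_month"

  ## rule 6 needs the cell's monthly MLD; off-grid or undefined -> untestable
  cells <- latlon_to_cell(env$grid, lat, lon_norm)
  ok_cell <- !is.na(cells$lat_idx) & !is.na(cells$lon_idx) & !r5
  mld <- rep(NA_real_, n)
  if (any(ok_cell)) {
    mld[ok_cell] <- env_field(env, "MLD")[
      cellmonth_index(env$grid, mo[ok_cell],
                      cells$lat_idx[ok_cell], cells$lon_idx[ok_cell])]
  }
  r6 <- !is.na(dp) & !is.na(mld) & dp > mld
  rule[is.na(rule) & r6] <- "below_mixed_layer"

  ## mixed-layer species: >= 1 retained record with known depth within MLD
  in_ml <- is.na(rule) & !is.na(dp) & !is.na(mld) & dp <= mld
  ml_species <- unique(records$scientificName[in_ml])
  r7 <- is.na(dp) & !(records$scientificName %in% ml_species)
  rule[is.na(rule) & r7] <- "depth_missing_no_ml_evidence"

  keep <- is.na(rule)
  out <- records[keep, , drop = FALSE]
  out$decimalLongitude <- lon_norm[keep]
  rules <- c("fossil_preserved", "year_out_of_range", "negative_depth",
             "bad_coordinates", "missing_month", "below_mixed_layer",
             "depth_missing_no_ml_evidence")
  list(records = out,
       report = filter_report(rule, rules, n))
}

#' Filter report
#'
#' Per-rule removal counts for a cleaning step.  Counts are exhaustive and
#' exclusive: `sum(removed) + retained == input rows`.
#'
#' @param rule Character vector of first-failing rule per row (`NA` =
#'   retained).
#' @param rules Ordered rule names.
#' @param n_input Number of input rows.
#' @return A list of class `filter_report` with `removed` (named integer
#'   vector), `retained` and `n_input`.
#' @export
filter_report <- function(rule, rules, n_input) {
  removed <- vapply(rules, function(r) sum(rule == r, na.rm = TRUE),
                    integer(1))
  structure(list(removed = removed,
                 retained = n_input - sum(removed),
                 n_input = n_input),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d rows in, %d retained\n",
              x$n_input, x$retained))
  for (r in names(x$removed))
    if (x$removed[[r]] > 0)
      cat(sprintf("  %-28s %d removed\n", r, x$removed[[r]]))
  invisible(x)
}

#' @rdname filter_report
#' @param report A `filter_report`.
#' @param path File path for a JSON serialisation.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(list(removed = as.list(report$removed),
                            retained = report$retained,
                            n_input = report$n_input),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Restrict records to the open ocean
#'
#' Removes rows in cells with bathymetry shallower than `min_depth` m or
#' surface salinity below `min_salinity` (rule order: off-grid, missing
#' bathymetry, shallow, brackish; each row attributed to its first failure).
#'
#' @param records An `occurrence_table` (coordinates already normalised).
#' @param env An [env_clim()] with `bathymetry` and `S` fields.
#' @param min_depth Minimum bottom depth in metres (default 200).
#' @param min_salinity Minimum surface salinity (default 20).
#' @param drop_missing_bathymetry Exclude rows whose cell has no bathymetry
#'   value (default `TRUE`; counted separately).
#' @return A list with `records` and `report`.
#' @export
apply_open_ocean_mask <- function(records, env, min_depth = 200,
                                  min_salinity = 20,
                                  drop_missing_bathymetry = TRUE) {
  stopifnot(inherits(env, "env_clim"))
  n <- nrow(records)
  rule <- rep(NA_character_, n)
  cells <- latlon_to_cell(env$grid, records$decimalLatitude,
                          records$decimalLongitude)
  off <- is.na(cells$lat_idx) | is.na(cells$lon_idx)
  rule[off] <- "outside_grid"

  bathy <- rep(NA_real_, n)
  sal <- rep(NA_real_, n)
  ok <- !off
  if (any(ok)) {
    mo <- pmin(pmax(suppressWarnings(as.integer(records$month)), 1L), 12L)
    mo[is.na(mo)] <- 1L
    idx <- cellmonth_index(env$grid, mo[ok], cells$lat_idx[ok],
                           cells$lon_idx[ok])
    bathy[ok] <- env_field(env, "bathymetry")[idx]
    sal[ok] <- env_field(env, "S")[idx]
  }
  if (drop_missing_bathymetry)
    rule[is.na(rule) & ok & is.na(bathy)] <- "missing_bathymetry"
  rule[is.na(rule) & !is.na(bathy) & bathy < min_depth] <- "shallow_sea"
  rule[is.na(rule) & !is.na(sal) & sal < min_salinity] <- "low_salinity"

  keep <- is.na(rule)
  rules <- c("outside_grid", "missing_bathymetry", "shallow_sea",
             "low_salinity")
  list(records = records[keep, , drop = FALSE],
       report = filter_report(rule, rules, n))
}

#' Bin presences to monthly 1-degree cells
#'
#' Multiple records of a species in the same cell and calendar month --
#' potentially from different years or days -- count as a single presence.
#'
#' @param records An `occurrence_table` (cleaned; coordinates normalised).
#' @param spec A [grid_spec()].
#' @return A data frame of class `gridded_presences` with unique rows
#'   `(species_id, month, lat_idx, lon_idx)`, the grid in `attr(, "grid")`
#'   and per-species presence totals in `attr(, "counts")`.
#' @export
bin_presences <- function(records, spec) {
  stopifnot(is_grid_spec(spec))
  if (nrow(records) == 0) {
    out <- data.frame(species_id = character(0), month = integer(0),
                      lat_idx = integer(0), lon_idx = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    cells <- latlon_to_cell(spec, records$decimalLatitude,
                            records$decimalLongitude)
    out <- data.frame(species_id = records$scientificName,
                      month = as.integer(records$month),
                      lat_idx = cells$lat_idx, lon_idx = cells$lon_idx,
                      stringsAsFactors = FALSE)
    out <- out[stats::complete.cases(out), , drop = FALSE]
    out <- unique(out)
    out <- out[order(out$species_id, out$month, out$lat_idx, out$lon_idx), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  counts <- table(factor(out$species_id))
  structure(out, grid = spec,
            counts = stats::setNames(as.integer(counts), names(counts)),
            class = c("gridded_presences", "data.frame"))
}

#' @rdname bin_presences
#' @param presences A `gridded_presences`.
#' @export
presence_counts <- function(presences) attr(presences, "counts")

#' @rdname bin_presences
#' @param path File path for the CSV serialisation.
#' @export
write_presences <- function(presences, path) {
  utils::write.csv(as.data.frame(presences), path, row.names = FALSE)
  invisible(path)
}

#' Spatially thin records of each species
#'
#' First-come greedy thinning: records are scanned in input order and a
#' record is retained only when it lies at least `min_km` (great-circle,
#' haversine on a 6371 km sphere) from every record of the same species
#' already retained.  Used for ranking sensitivity analyses, not the main
#' pipeline.  `seed` permutes the scan order per species when
#' `randomize_order = TRUE`; the default keeps input order so results are
#' reproducible without a seed.
#'
#' @param records An `occurrence_table`.
#' @param min_km Minimum pairwise distance in kilometres (> 0).
#' @param seed Integer seed (only used when `randomize_order = TRUE`).
#' @param randomize_order Scan records in seeded random order instead of
#'   input order.
#' @return The thinned `occurrence_table`.
#' @export
thin_presences <- function(records, min_km, seed = 1,
                           randomize_order = FALSE) {
  stopifnot(min_km > 0)
  if (nrow(records) == 0) return(records)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  keep <- logical(nrow(records))
  for (sp in unique(records$scientificName)) {
    ri <- which(records$scientificName == sp)
    if (randomize_order) ri <- sample(ri)
    kept <- integer(0)
    for (i in ri) {
      if (length(kept) == 0) {
        kept <- i; next
      }
      d <- geosphere::distHaversine(
        cbind(records$decimalLongitude[i], records$decimalLatitude[i]),
        cbind(records$decimalLongitude[kept], records$decimalLatitude[kept]),
        r = 6371000)
      if (all(d >= min_km * 1000)) kept <- c(kept, i)
    }
    keep[kept] <- TRUE
  }
  records[sort(which(keep)), , drop = FALSE]
}
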