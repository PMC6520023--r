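#' Build target groups for pseudoabsence sampling
#'
#' The target-group approach draws a species' pseudoabsences from the pooled
#' presence cells of a broad group of taxa sampled by the same community, so
#' background data inherit the same spatial and seasonal sampling bias as the
#' presences.  In `"group-specific"` mode, diatoms (Bacillariophyceae),
#' dinoflagellates and haptophytes each use their own taxon's pooled cells;
#' species of all remaining taxa use the pool of all species excluding
#' diatoms (whose sampling is strongly north-south imbalanced).  In
#' `"total"` mode every species uses the pool of all species.  Species with
#' an unknown taxon in group-specific mode fall back to the total pool with
#' a warning.
#'
#' @param presences A [bin_presences()] result.
#' @param group_map Named character vector mapping `species_id` to taxon.
#' @param mode `"group-specific"` or `"total"`.
#' @return A named list (one entry per species) of class `target_groups`;
#'   each entry is a data frame of monthly cells `(month, lat_idx, lon_idx)`
#'   with a `weight` column counting the distinct species-presences in that
#'   cell (multiplicity).
#' @export
build_target_group <- function(presences, group_map,
                               mode = c("group-specific", "total")) {
  mode <- match.arg(mode)
  species <- unique(presences$species_id)
  if (!all(species %in% names(group_map)) && mode == "total")
    group_map[setdiff(species, names(group_map))] <- "unknown"

  pool_cells <- function(sub) {
    if (nrow(sub) == 0) return(NULL)
    k <- key_string(sub$month, sub$lat_idx, sub$lon_idx)
    agg <- table(k)
    first <- sub[!duplicated(k), c("month", "lat_idx", "lon_idx")]
    first$weight <- as.integer(agg[key_string(first$month, first$lat_idx,
                                              first$lon_idx)])
    rownames(first) <- NULL
    first
  }

  taxa <- group_map[presences$species_id]
  if (mode == "total") {
    total <- pool_cells(presences)
    out <- stats::setNames(rep(list(total), length(species)), species)
  } else {
    own_taxa <- c("Bacillariophyceae", "Dinoflagellata", "Haptophyta")
    rest_pool <- pool_cells(presences[!is.na(taxa) &
                                        taxa != "Bacillariophyceae", ,
                                      drop = FALSE])
    total_pool <- NULL
    out <- vector("list", length(species))
    names(out) <- species
    for (sp in species) {
      tx <- group_map[[sp]] %||% NA_character_
      if (is.na(tx) || !nzchar(tx)) {
        warning(sprintf(
          "build_target_group: species '%s' has unknown taxon; using total pool",
          sp))
        if (is.null(total_pool)) total_pool <- pool_cells(presences)
        out[[sp]] <- total_pool
      } else if (tx %in% own_taxa) {
        out[[sp]] <- pool_cells(presences[!is.na(taxa) & taxa == tx, ,
                                          drop = FALSE])
      } else {
        out[[sp]] <- rest_pool
      }
    }
  }
  structure(out, mode = mode, class = "target_groups")
}

#' Stratify target-group cells by temperature and mixed-layer depth
#'
#' The temperature and mixed-layer-depth spans of the target group's monthly
#' cells are each divided into `n_bins` equal-width intervals (maximum edge
#' inclusive), crossing to `n_bins^2` strata (81 with the default 9 bins).
#' Cells with missing T or MLD are dropped and counted.  A degenerate span
#' (all values equal) collapses that axis to a single bin with a warning.
#'
#' @param group One target group (data frame of monthly cells).
#' @param env An [env_clim()] with `T` and `MLD`.
#' @param n_bins Bins per axis (default 9).
#' @return A list of class `stratum_assignment`: `cells` (the usable cells
#'   with `t_bin`, `mld_bin`, `stratum`), `t_edges`, `mld_edges`,
#'   `n_strata`, `n_dropped`.
#' @export
stratify <- function(group, env, n_bins = 9) {
  stopifnot(n_bins >= 1, inherits(env, "env_clim"))
  vals <- env_matchup(env, group, c("T", "MLD"))
  ok <- stats::complete.cases(vals)
  cells <- group[ok, , drop = FALSE]
  tv <- vals$T[ok]; mv <- vals$MLD[ok]
  if (nrow(cells) == 0) stop("stratify: no cells with both T and MLD")

  axis_bins <- function(x, label) {
    lo <- min(x); hi <- max(x)
    if (lo == hi) {
      warning(sprintf("stratify: degenerate %s span; single bin", label))
      list(edges = c(lo, hi), bin = rep(1L, length(x)), n = 1L)
    } else {
      edges <- seq(lo, hi, length.out = n_bins + 1)
      bin <- findInterval(x, edges, rightmost.closed = TRUE,
                          all.inside = TRUE)
      list(edges = edges, bin = as.integer(bin), n = as.integer(n_bins))
    }
  }
  tb <- axis_bins(tv, "temperature")
  mb <- axis_bins(mv, "MLD")
  cells$t_bin <- tb$bin
  cells$mld_bin <- mb$bin
  cells$stratum <- (tb$bin - 1L) * mb$n + mb$bin
  structure(list(cells = cells, t_edges = tb$edges, mld_edges = mb$edges,
                 n_strata = tb$n * mb$n, n_t_bins = tb$n, n_mld_bins = mb$n,
                 n_dropped = sum(!ok)),
            class = "stratum_assignment")
}

#' Draw stratified background (pseudoabsence) data for one species
#'
#' The target amount is `ratio` times the species' presence count.  The
#' candidate pool is the target group's presence data gridded to distinct
#' monthly 1-degree cells -- only cells the group's sampling visited can
#' become background, which is how the background inherits the presences'
#' sampling bias.  Each stratum receives a quota proportional to the
#' number of monthly cells the target group provides in it
#' (largest-remainder rounding, so realised quotas sum exactly to the
#' target when enough cells are available); within a stratum, cells are
#' sampled uniformly at random without replacement, and the species' own
#' presence cells are excluded.  If a stratum cannot fill its quota the
#' deficit is redistributed proportionally over the strata that still
#' have cells; if the whole pool is exhausted the realised size falls
#' short with a warning.
#'
#' @param species_id The focal species.
#' @param presences A [bin_presences()] result (for the presence count and
#'   the exclusion of presence cells).
#' @param strata A [stratify()] result for the species' target group.
#' @param ratio Background-to-presence ratio (default 10).
#' @param seed Integer seed.
#' @return A data frame of class `background_set` with columns `species_id`,
#'   `month`, `lat_idx`, `lon_idx`, `stratum`, plus attributes `target_size`
#'   and `realized_size`.
#' @export
sample_background <- function(species_id, presences, strata, ratio = 10,
                              seed = 1) {
  stopifnot(inherits(strata, "stratum_assignment"), ratio >= 1)
  n_pres <- sum(presences$species_id == species_id)
  if (n_pres == 0)
    stop(sprintf("sample_background: species '%s' has no presences",
                 species_id))
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  target <- as.integer(round(ratio * n_pres))
  cells <- strata$cells
  own <- presences[presences$species_id == species_id, , drop = FALSE]
  own_keys <- key_string(own$month, own$lat_idx, own$lon_idx)
  cell_keys <- key_string(cells$month, cells$lat_idx, cells$lon_idx)
  avail <- cells[!(cell_keys %in% own_keys), , drop = FALSE]
  if (nrow(avail) == 0)
    stop("sample_background: no admissible background cells")

  ## quotas proportional to target-group monthly cells per stratum
  sid <- sort(unique(cells$stratum))
  weight <- vapply(sid, function(s)
    sum(cells$stratum == s), numeric(1))
  quota <- largest_remainder(weight, target)

  pick <- integer(0)
  remaining <- split(seq_len(nrow(avail)), factor(avail$stratum,
                                                  levels = sid))
  need <- stats::setNames(quota, sid)
  repeat {
    for (s in as.character(sid)) {
      k <- min(need[[s]], length(remaining[[s]]))
      if (k > 0) {
        take <- if (length(remaining[[s]]) == 1) remaining[[s]] else
          sample(remaining[[s]], k)
        pick <- c(pick, take)
        remaining[[s]] <- setdiff(remaining[[s]], take)
        need[[s]] <- need[[s]] - k
      }
    }
    deficit <- sum(need)
    capacity <- vapply(remaining, length, integer(1))
    if (deficit == 0 || sum(capacity) == 0) break
    ## redistribute the deficit over strata that still have cells
    add <- largest_remainder(pmin(capacity, deficit), deficit)
    need <- stats::setNames(pmin(add, capacity), sid)
    if (sum(need) == 0) break
  }
  if (length(pick) < target)
    warning(sprintf(
      "sample_background: %s: only %d of %d background cells available",
      species_id, length(pick), target))

  out <- avail[sort(pick), c("month", "lat_idx", "lon_idx", "stratum")]
  out <- data.frame(species_id = species_id, out, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out, target_size = target,
            realized_size = nrow(out),
            class = c("background_set", "data.frame"))
}
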