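#' Taxon-balancing species weights
#'
#' When the modelled species cover taxa unevenly, each species of taxon `g`
#' is weighted by `known_g / modeled_g` (the inverse of the taxon's
#' modelled fraction), normalised so the weights sum to the total number of
#' modelled species.  Taxa with zero modelled species contribute nothing.
#'
#' @param modeled Named integer vector: modelled species per taxon.
#' @param known Named integer vector on the same taxa: totally known
#'   species per taxon (`known >= modeled`).
#' @param species_taxon Named character vector mapping each modelled
#'   `species_id` to its taxon.
#' @return Named numeric vector of per-species weights.
#' @export
taxon_weights <- function(modeled, known, species_taxon) {
  stopifnot(all(names(modeled) %in% names(known)))
  if (any(known[names(modeled)] < modeled))
    stop("taxon_weights: known must be >= modeled for every taxon")
  keep <- modeled > 0
  ratio <- known[names(modeled)][keep] / modeled[keep]
  w_taxon <- stats::setNames(as.numeric(ratio), names(modeled)[keep])
  w <- w_taxon[species_taxon]
  w <- w * length(species_taxon) / sum(w)
  stats::setNames(as.numeric(w), names(species_taxon))
}

#' Stack ensemble projections into a species-richness map
#'
#' Monthly expected richness per cell is the (optionally weighted) sum of
#' the species' ensemble values; the annual map is the mean over months
#' with data.  Cells covered in fewer than 12 months are flagged.
#'
#' @param ensembles A list of `ensemble_projection` objects on one grid.
#' @param weights Optional per-species weights, in the order of
#'   `ensembles` or named by `species_id` (default: all 1).
#' @return A list of class `richness_map`: `monthly` (a `(12, n_lat,
#'   n_lon)` array), `annual` (matrix), `months_covered` (matrix) and
#'   `full_coverage` (logical matrix, `TRUE` where all 12 months have
#'   data).
#' @export
stack_richness <- function(ensembles, weights = NULL) {
  ensembles <- Filter(Negate(is.null), ensembles)
  if (length(ensembles) == 0) stop("stack_richness: no ensembles")
  dims <- dim(ensembles[[1]]$values)
  ids <- vapply(ensembles, function(e) e$species_id, character(1))
  if (is.null(weights)) weights <- rep(1, length(ensembles))
  if (!is.null(names(weights))) weights <- weights[ids]
  stopifnot(length(weights) == length(ensembles), all(!is.na(weights)))

  monthly <- array(0, dim = dims)
  any_data <- array(FALSE, dim = dims)
  for (i in seq_along(ensembles)) {
    v <- ensembles[[i]]$values
    stopifnot(identical(dim(v), dims))
    has <- !is.na(v)
    any_data <- any_data | has
    v[!has] <- 0
    monthly <- monthly + weights[i] * v
  }
  monthly[!any_data] <- NA_real_
  months_covered <- apply(any_data, c(2, 3), sum)
  annual <- apply(monthly, c(2, 3), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  structure(list(monthly = monthly, annual = annual,
                 months_covered = months_covered,
                 full_coverage = months_covered == 12,
                 weights = stats::setNames(weights, ids)),
            class = "richness_map")
}

#' Jaccard turnover component between two communities
#'
#' The species-replacement part of Jaccard dissimilarity: with `a` shared
#' species and `b`, `c` species unique to either side, the turnover
#' component is `2 * min(b, c) / (a + 2 * min(b, c))`.  It is 0 for
#' identical or purely nested communities, 1 for disjoint nonempty
#' communities, and undefined (error) when both communities are empty.
#'
#' @param A,B Vectors of species identifiers (sets).
#' @return The turnover component in `[0, 1]`.
#' @export
jaccard_turnover <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (length(A) == 0 && length(B) == 0)
    stop("jaccard_turnover: undefined for two empty communities")
  a <- sum(A %in% B)
  b <- length(A) - a
  c <- length(B) - a
  m <- min(b, c)
  if (a + 2 * m == 0) return(0)   # pure nestedness or total loss/gain
  2 * m / (a + 2 * m)
}

#' Month-to-month species-turnover map
#'
#' Communities are derived from the monthly ensemble values: a species is
#' present in a cell when its value strictly exceeds `presence_cut`.
#' Turnover is computed for the 12 consecutive month pairs (including the
#' December-January wrap by default) and averaged per cell over the pairs
#' where at least one of the two communities is nonempty; cell-months
#' without data invalidate the pairs touching them.
#'
#' @param ensembles A list of `ensemble_projection` objects.
#' @param presence_cut Strict presence threshold on ensemble values
#'   (default 0.5).
#' @param wrap Include the December-January pair (default `TRUE`, giving
#'   exactly 12 pairs).
#' @return A list of class `turnover_map`: `mean` (matrix of per-cell mean
#'   turnover), `pairs` (a `(n_pairs, n_lat, n_lon)` array) and `n_pairs`.
#' @export
turnover_map <- function(ensembles, presence_cut = 0.5, wrap = TRUE) {
  ensembles <- Filter(Negate(is.null), ensembles)
  if (length(ensembles) == 0) stop("turnover_map: no ensembles")
  dims <- dim(ensembles[[1]]$values)
  n_cell <- dims[2] * dims[3]
  n_sp <- length(ensembles)

  ## per month: cell x species presence and validity
  pres <- lapply(1:12, function(m) {
    matrix(vapply(ensembles, function(e)
      as.vector(e$values[m, , ]) > presence_cut, logical(n_cell)),
      nrow = n_cell)
  })
  valid <- lapply(1:12, function(m) {
    rowSums(matrix(vapply(ensembles, function(e)
      !is.na(as.vector(e$values[m, , ])), logical(n_cell)),
      nrow = n_cell)) == n_sp
  })

  pairs_idx <- if (wrap) cbind(1:12, c(2:12, 1)) else cbind(1:11, 2:12)
  pair_vals <- array(NA_real_, dim = c(nrow(pairs_idx), dims[2], dims[3]))
  for (p in seq_len(nrow(pairs_idx))) {
    m1 <- pairs_idx[p, 1]; m2 <- pairs_idx[p, 2]
    A <- pres[[m1]]; B <- pres[[m2]]
    AB <- A & B
    a <- rowSums(AB)
    b <- rowSums(A) - a
    c <- rowSums(B) - a
    m <- pmin(b, c)
    tv <- ifelse(a + 2 * m == 0,
                 ifelse(a + b + c == 0, NA_real_, 0),
                 2 * m / (a + 2 * m))
    tv[!(valid[[m1]] & valid[[m2]])] <- NA_real_
    pair_vals[p, , ] <- matrix(tv, dims[2], dims[3])
  }
  mean_tv <- apply(pair_vals, c(2, 3), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  structure(list(mean = mean_tv, pairs = pair_vals,
                 n_pairs = nrow(pairs_idx)),
            class = "turnover_map")
}

#' Monte Carlo uncertainty from predictor-set choice
#'
#' Each run selects, for every species independently, one of its retained
#' member models at random (one predictor set) and recomputes richness --
#' and optionally turnover -- from the selected members' binary
#' projections.  The per-cell mean and standard deviation over runs
#' quantify the uncertainty contributed by predictor-set choice.
#'
#' @param fits A list of [fit_species_sdm()] results (their `set_maps`
#'   hold the retained members' binary projections).
#' @param n_runs Number of runs (the full design uses 1000; reduced runs
#'   are adequate for desk-scale grids).
#' @param seed Integer seed; identical seeds give identical summaries.
#' @param include_turnover Also recompute the turnover map per run.
#' @param presence_cut Presence threshold for turnover communities.
#' @return A list of class `monte_carlo_summary`: `richness_mean`,
#'   `richness_sd` (matrices, annual-mean richness across runs),
#'   `turnover_mean`, `turnover_sd` (or `NULL`), `n_runs`, `n_species`,
#'   `n_failed`.
#' @export
monte_carlo_diversity <- function(fits, n_runs = 1000, seed = 1,
                                  include_turnover = FALSE,
                                  presence_cut = 0.5) {
  stopifnot(n_runs >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  usable <- Filter(function(f) {
    any(vapply(f$set_maps, Negate(is.null), logical(1)))
  }, fits)
  n_failed <- length(fits) - length(usable)
  if (length(usable) == 0) stop("monte_carlo_diversity: no retained members")

  options_per_sp <- lapply(usable, function(f)
    which(vapply(f$set_maps, Negate(is.null), logical(1))))
  dims <- dim(usable[[1]]$set_maps[[options_per_sp[[1]][1]]])

  r_sum <- matrix(0, dims[2], dims[3])
  r_sq <- matrix(0, dims[2], dims[3])
  t_sum <- matrix(0, dims[2], dims[3]); t_sq <- t_sum
  t_n <- matrix(0L, dims[2], dims[3])
  r_n <- matrix(0L, dims[2], dims[3])

  for (run in seq_len(n_runs)) {
    pick <- vapply(options_per_sp, function(opt)
      if (length(opt) == 1) opt else sample(opt, 1), integer(1))
    monthly <- array(0, dim = dims)
    any_data <- array(FALSE, dim = dims)
    for (i in seq_along(usable)) {
      v <- usable[[i]]$set_maps[[pick[i]]]
      has <- !is.na(v)
      any_data <- any_data | has
      v[!has] <- 0
      monthly <- monthly + v
    }
    monthly[!any_data] <- NA_real_
    annual <- apply(monthly, c(2, 3), function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    has_r <- !is.na(annual)
    r_sum[has_r] <- r_sum[has_r] + annual[has_r]
    r_sq[has_r] <- r_sq[has_r] + annual[has_r]^2
    r_n <- r_n + has_r

    if (include_turnover) {
      ens <- lapply(seq_along(usable), function(i)
        structure(list(species_id = usable[[i]]$species_id,
                       values = usable[[i]]$set_maps[[pick[i]]],
                       n_retained = 1L),
                  class = "ensemble_projection"))
      tv <- turnover_map(ens, presence_cut = presence_cut)$mean
      has_t <- !is.na(tv)
      t_sum[has_t] <- t_sum[has_t] + tv[has_t]
      t_sq[has_t] <- t_sq[has_t] + tv[has_t]^2
      t_n <- t_n + has_t
    }
  }
  msd <- function(s, q, n) {
    mean <- ifelse(n > 0, s / n, NA_real_)
    var <- ifelse(n > 1, pmax(q / n - mean^2, 0) * n / (n - 1), 0)
    list(mean = mean, sd = sqrt(var))
  }
  r <- msd(r_sum, r_sq, r_n)
  tv <- if (include_turnover) msd(t_sum, t_sq, t_n) else NULL
  structure(list(richness_mean = r$mean, richness_sd = r$sd,
                 turnover_mean = tv$mean %||% NULL,
                 turnover_sd = tv$sd %||% NULL,
                 n_runs = n_runs, n_species = length(usable),
                 n_failed = n_failed, seed = seed),
            class = "monte_carlo_summary")
}

#' Export gridded diversity maps as long-format CSV
#'
#' @param richness A [stack_richness()] result.
#' @param turnover Optional [turnover_map()] result.
#' @param path File path.
#' @export
write_diversity_maps <- function(richness, path, turnover = NULL) {
  ann <- richness$annual
  idx <- which(!is.na(ann), arr.ind = TRUE)
  out <- data.frame(lat_idx = idx[, 1], lon_idx = idx[, 2],
                    richness_annual = ann[idx],
                    months_covered = richness$months_covered[idx])
  if (!is.null(turnover))
    out$turnover_mean <- turnover$mean[idx]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
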