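#' Thermal-regime regressions of log richness on inverse thermal energy
#'
#' The metabolic theory of ecology predicts that the natural logarithm of
#' species richness declines linearly with inverse thermal energy
#' `1/(kT)` (k = Boltzmann's constant, 8.617e-5 eV/K; T in kelvin) with a
#' slope of about -0.32 eV.  This fits ordinary least squares of
#' `ln(richness)` on `1/(kT)` globally and within thermal regimes split at
#' the given breakpoints in degrees C (defaults 11 and 19, i.e. warm
#' `T >= 19`, transitional `11 <= T < 19`, cold `T < 11`).
#'
#' @param richness Per-cell (annual mean) richness; must be positive to
#'   enter the log (nonpositive and missing cells are dropped).
#' @param temperature Per-cell (annual mean) temperature in degrees C,
#'   aligned with `richness`.
#' @param breakpoints Increasing breakpoints in degrees C.
#' @param min_cells Minimum cells per regime; sparser regimes are skipped
#'   and reported with `NA` estimates.
#' @return A data frame of class `regime_fit` with rows `global` plus one
#'   per regime: `regime`, `t_min`, `t_max`, `slope` (per eV), `intercept`,
#'   `r_squared`, `n`.
#' @export
fit_thermal_regimes <- function(richness, temperature,
                                breakpoints = c(11, 19), min_cells = 3) {
  stopifnot(length(richness) == length(temperature),
            !is.unsorted(breakpoints))
  ok <- is.finite(richness) & is.finite(temperature) & richness > 0
  r <- richness[ok]; tc <- temperature[ok]
  x <- 1 / (boltzmann_k() * (tc + 273.15))
  y <- log(r)

  edges <- c(-Inf, breakpoints, Inf)
  fit_one <- function(sel, label, lo, hi) {
    n <- sum(sel)
    if (n < min_cells)
      return(data.frame(regime = label, t_min = lo, t_max = hi,
                        slope = NA_real_, intercept = NA_real_,
                        r_squared = NA_real_, n = n))
    m <- stats::lm(y[sel] ~ x[sel])
    data.frame(regime = label, t_min = lo, t_max = hi,
               slope = unname(stats::coef(m)[2]),
               intercept = unname(stats::coef(m)[1]),
               r_squared = summary(m)$r.squared, n = n)
  }
  rows <- list(fit_one(rep(TRUE, length(x)), "global", -Inf, Inf))
  for (i in seq_len(length(edges) - 1)) {
    lo <- edges[i]; hi <- edges[i + 1]
    sel <- tc >= lo & tc < hi
    label <- if (!is.finite(lo)) sprintf("T < %g", hi)
    else if (!is.finite(hi)) sprintf("T >= %g", lo)
    else sprintf("%g <= T < %g", lo, hi)
    rows[[length(rows) + 1]] <- fit_one(sel, label, lo, hi)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, breakpoints = breakpoints,
            class = c("regime_fit", "data.frame"))
}

#' Data-driven search for two thermal breakpoints
#'
#' Grid search over breakpoint pairs minimising the pooled residual sum of
#' squares of the three per-regime regressions; a sensitivity companion to
#' the fixed defaults of [fit_thermal_regimes()].
#'
#' @inheritParams fit_thermal_regimes
#' @param grid Candidate breakpoints in degrees C.
#' @param min_gap Minimum separation between the two breakpoints.
#' @return The [fit_thermal_regimes()] result at the best pair, with the
#'   pair in `attr(, "breakpoints")`.
#' @export
search_thermal_breakpoints <- function(richness, temperature,
                                       grid = seq(5, 25, by = 1),
                                       min_gap = 3, min_cells = 10) {
  best <- NULL; best_sse <- Inf
  ok <- is.finite(richness) & is.finite(temperature) & richness > 0
  r <- richness[ok]; tc <- temperature[ok]
  x <- 1 / (boltzmann_k() * (tc + 273.15)); y <- log(r)
  for (b1 in grid) for (b2 in grid[grid >= b1 + min_gap]) {
    sse <- 0; okpair <- TRUE
    for (sel in list(tc < b1, tc >= b1 & tc < b2, tc >= b2)) {
      if (sum(sel) < min_cells) { okpair <- FALSE; break }
      m <- stats::lm(y[sel] ~ x[sel])
      sse <- sse + sum(stats::resid(m)^2)
    }
    if (okpair && sse < best_sse) { best_sse <- sse; best <- c(b1, b2) }
  }
  if (is.null(best)) stop("search_thermal_breakpoints: no admissible pair")
  fit_thermal_regimes(richness, temperature, breakpoints = best,
                      min_cells = min_cells)
}

#' Univariate explanatory power of a predictor for richness
#'
#' Fits richness as a linear-plus-quadratic function of a single predictor
#' (Gaussian family) and returns the R-squared; the table of these scores
#' across predictors identifies the dominant environmental driver.
#'
#' @param response Richness values (per cell or per sample).
#' @param predictor Predictor values aligned with `response`.
#' @param min_n Minimum paired observations (default 10).
#' @return The R-squared (0 for a constant predictor).
#' @export
single_variable_power <- function(response, predictor, min_n = 10) {
  ok <- is.finite(response) & is.finite(predictor)
  if (sum(ok) < min_n)
    stop("single_variable_power: fewer than min_n paired values")
  y <- response[ok]; x <- predictor[ok]
  if (stats::var(x) == 0) return(0)
  summary(stats::lm(y ~ x + I(x^2)))$r.squared
}

#' @rdname single_variable_power
#' @param data Data frame holding the predictors.
#' @param predictors Column names to score.
#' @return `single_variable_power_table`: a data frame `predictor`,
#'   `r_squared`, sorted descending.
#' @export
single_variable_power_table <- function(response, data, predictors,
                                        min_n = 10) {
  r2 <- vapply(predictors, function(v)
    single_variable_power(response, data[[v]], min_n = min_n), numeric(1))
  out <- data.frame(predictor = predictors, r_squared = r2,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$r_squared), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rarefied species richness of raw observations by stratum
#'
#' Counteracts uneven sampling effort in the raw records: samples (unique
#' combinations of latitude, longitude, depth, year, month and day) are
#' drawn at random without replacement, `n_per_stratum` from each stratum,
#' the draws are pooled per stratum and the distinct species counted;
#' repeated `n_reps` times.  Strata holding fewer samples than
#' `n_per_stratum` are excluded and reported.
#'
#' @param records An `occurrence_table`.
#' @param strata Vector (length `nrow(records)`) of stratum labels per
#'   record, e.g. latitude bands or environmental bins.
#' @param n_per_stratum Samples drawn per stratum and repetition.
#' @param n_reps Repetitions.
#' @param seed Integer seed.
#' @return A data frame of class `rarefied_richness`: `stratum`,
#'   `n_samples`, `mean_richness`, `sd_richness`; excluded strata are kept
#'   in `attr(, "excluded")`.
#' @export
rarefied_raw_richness <- function(records, strata, n_per_stratum,
                                  n_reps = 100, seed = 1) {
  stopifnot(length(strata) == nrow(records), n_per_stratum >= 1,
            n_reps >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  sample_id <- paste(records$decimalLatitude, records$decimalLongitude,
                     records$depth, records$year, records$month,
                     records$day, sep = "|")
  out <- list(); excluded <- character(0)
  for (s in unique(as.character(strata))) {
    rows <- which(as.character(strata) == s)
    ids <- unique(sample_id[rows])
    if (length(ids) < n_per_stratum) {
      excluded <- c(excluded, s)
      next
    }
    rich <- vapply(seq_len(n_reps), function(rep) {
      take <- if (length(ids) == 1) ids else sample(ids, n_per_stratum)
      length(unique(records$scientificName[rows][sample_id[rows] %in% take]))
    }, numeric(1))
    out[[s]] <- data.frame(stratum = s, n_samples = length(ids),
                           mean_richness = mean(rich),
                           sd_richness = stats::sd(rich),
                           stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(stratum = character(0), n_samples = integer(0),
               mean_richness = numeric(0), sd_richness = numeric(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, excluded = excluded,
            class = c("rarefied_richness", "data.frame"))
}

#' Observed environmental range of a species
#'
#' The range is defined by the extremes of the environmental values matched
#' to the species' records (e.g. monthly 1-degree temperature at its
#' occurrences); the median describes the range centre.
#'
#' @param values Environmental values matched to one species' records
#'   (missing values dropped).
#' @return A named numeric vector `min`, `max`, `median`.
#' @export
observed_range <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0)
    stop("observed_range: no matchable records")
  c(min = min(v), max = max(v), median = stats::median(v))
}

#' @rdname observed_range
#' @param records An `occurrence_table`.
#' @param env An [env_clim()].
#' @param var Environmental variable to match at the records' monthly
#'   cells, or `"latitude"` for latitudinal ranges from the raw
#'   coordinates.
#' @return `species_observed_ranges`: data frame `species_id`, `n`,
#'   `min`, `max`, `median` (species with no matchable records are
#'   dropped and reported in `attr(, "unmatched")`).
#' @export
species_observed_ranges <- function(records, env, var = "T") {
  vals <- if (identical(var, "latitude")) records$decimalLatitude
  else {
    cells <- latlon_to_cell(env$grid, records$decimalLatitude,
                            records$decimalLongitude)
    keys <- data.frame(month = as.integer(records$month),
                       lat_idx = cells$lat_idx, lon_idx = cells$lon_idx)
    ok <- stats::complete.cases(keys)
    v <- rep(NA_real_, nrow(records))
    v[ok] <- env_matchup(env, keys[ok, ], var)[[1]]
    v
  }
  sp <- split(vals, records$scientificName)
  rows <- lapply(names(sp), function(s) {
    v <- sp[[s]][is.finite(sp[[s]])]
    if (length(v) == 0) return(NULL)
    data.frame(species_id = s, n = length(v), min = min(v), max = max(v),
               median = stats::median(v), stringsAsFactors = FALSE)
  })
  unmatched <- names(sp)[vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, unmatched = unmatched,
            class = c("species_observed_ranges", "data.frame"))
}

#' Expected maximum richness and mean range size from range overlap
#'
#' At each value of the environmental gradient, expected maximum richness
#' is the number of species whose observed range covers the value, and
#' range size is the mean (with SD) of `max - min` over the covering
#' species.
#'
#' @param ranges Data frame with `min` and `max` per species (e.g. from
#'   [species_observed_ranges()]).
#' @param grid Numeric vector of gradient values to evaluate.
#' @return A data frame of class `range_curves`: `value`, `overlap`,
#'   `mean_range_size`, `sd_range_size` (the latter `NA` where no species
#'   covers the value).
#' @export
range_overlap_curves <- function(ranges, grid) {
  stopifnot(all(c("min", "max") %in% names(ranges)), nrow(ranges) >= 1)
  size <- ranges$max - ranges$min
  rows <- lapply(grid, function(v) {
    cover <- ranges$min <= v & v <= ranges$max
    n <- sum(cover)
    data.frame(value = v, overlap = n,
               mean_range_size = if (n) mean(size[cover]) else NA_real_,
               sd_range_size = if (n > 1) stats::sd(size[cover]) else
                 NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("range_curves", "data.frame"))
}

#' Randomisation null model for range-overlap curves
#'
#' Shuffles species labels across the matched records (preserving each
#' species' record count and the pooled environmental distribution),
#' recomputes observed ranges and the overlap/range-size curves per run,
#' and summarises the runs into a per-value mean and central 95 percent
#' envelope.  Gradient regions where the envelope excludes the null
#' model's own central-gradient level are flagged as likely edge-effect
#' artefacts; curves are conventionally reported only outside the flagged
#' regions.  The centre is taken as the middle 50 percent of the observed
#' gradient span.
#'
#' @param values Environmental values matched to the records.
#' @param species Species label per record.
#' @param grid Gradient values to evaluate (default: 64 points over the
#'   observed span).
#' @param n_runs Randomisation runs (default 100; fewer than 20 warns).
#' @param alpha Envelope tail probability (default 0.05).
#' @param seed Integer seed.
#' @return A list of class `range_null_model`: `grid`,
#'   `overlap` / `range_size` (each a data frame `value`, `mean`, `lower`,
#'   `upper`, `edge_flag`), `center_overlap`, `center_range_size`,
#'   `n_runs`.
#' @export
range_null_model <- function(values, species, grid = NULL, n_runs = 100,
                             alpha = 0.05, seed = 1) {
  ok <- is.finite(values) & !is.na(species)
  values <- values[ok]; species <- as.character(species[ok])
  if (length(values) == 0) stop("range_null_model: no matched records")
  if (n_runs < 20)
    warning("range_null_model: fewer than 20 runs gives an unstable ",
            "envelope")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  if (is.null(grid))
    grid <- seq(min(values), max(values), length.out = 64)

  ov <- matrix(NA_real_, n_runs, length(grid))
  rs <- matrix(NA_real_, n_runs, length(grid))
  for (run in seq_len(n_runs)) {
    shuffled <- sample(species)
    lo <- tapply(values, shuffled, min)
    hi <- tapply(values, shuffled, max)
    ranges <- data.frame(min = as.numeric(lo), max = as.numeric(hi))
    cur <- range_overlap_curves(ranges, grid)
    ov[run, ] <- cur$overlap
    rs[run, ] <- cur$mean_range_size
  }
  span <- range(values)
  centre <- grid >= span[1] + 0.25 * diff(span) &
    grid <= span[2] - 0.25 * diff(span)
  summarise <- function(m) {
    mean_v <- colMeans(m, na.rm = TRUE)
    lower <- apply(m, 2, stats::quantile, probs = alpha / 2, na.rm = TRUE,
                   names = FALSE)
    upper <- apply(m, 2, stats::quantile, probs = 1 - alpha / 2,
                   na.rm = TRUE, names = FALSE)
    centre_value <- mean(mean_v[centre])
    data.frame(value = grid, mean = mean_v, lower = lower, upper = upper,
               edge_flag = centre_value < lower | centre_value > upper)
  }
  ov_s <- summarise(ov)
  rs_s <- summarise(rs)
  structure(list(grid = grid, overlap = ov_s, range_size = rs_s,
                 center_overlap = mean(ov_s$mean[centre]),
                 center_range_size = mean(rs_s$mean[centre]),
                 n_runs = n_runs),
            class = "range_null_model")
}

#' Thermal response of an ensemble projection
#'
#' Bins the climatology's monthly temperatures and averages the species'
#' ensemble values per bin -- the realised thermal response curve.  The
#' reported peak is the response-weighted centroid of the bins at or
#' above half the maximum (robust to the flat-topped curves that
#' ensembles of few binary members produce); it is compared against the
#' species' true optimum in niche-recovery experiments.
#'
#' @param ensemble An `ensemble_projection`.
#' @param env The [env_clim()] the ensemble was projected on.
#' @param bin_width Temperature bin width in degrees C (default 1).
#' @return A data frame `t_mid`, `mean_value`, `n_cells`, with the peak
#'   bin centre in `attr(, "peak")`.
#' @export
ensemble_thermal_response <- function(ensemble, env, bin_width = 1) {
  tv <- as.vector(env_field(env, "T"))
  ev <- as.vector(ensemble$values)
  ok <- is.finite(tv) & is.finite(ev)
  tv <- tv[ok]; ev <- ev[ok]
  bin <- floor(tv / bin_width)
  agg <- tapply(ev, bin, mean)
  out <- data.frame(t_mid = (as.numeric(names(agg)) + 0.5) * bin_width,
                    mean_value = as.numeric(agg),
                    n_cells = as.integer(table(bin)))
  ## ensembles of few binary members plateau around the optimum, so a raw
  ## argmax is a noisy peak estimator; the response-weighted centroid of
  ## the region at or above half maximum locates the peak robustly
  top <- out$mean_value >= max(out$mean_value) / 2
  structure(out, peak = sum(out$t_mid[top] * out$mean_value[top]) /
              sum(out$mean_value[top]))
}
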