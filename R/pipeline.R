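#' Run the full diversity-mapping pipeline on simulated data
#'
#' End-to-end driver used for validation experiments: starting from a
#' virtual species pool with known niches, it (1) samples biased
#' presence-only records under an effort model, (2) cleans, masks and bins
#' them to monthly 1-degree presences, (3) draws stratified target-group
#' background data per species, (4) builds randomised low-correlation
#' predictor sets and fits, evaluates and projects the per-species member
#' models, and (5) stacks the retained ensembles into monthly and
#' annual-mean richness (and optionally turnover) maps restricted to the
#' open-ocean cells.  Species falling below `min_presences` presences, or
#' retaining no member, are excluded and reported.
#'
#' All stages derive their randomness from `seed`, so identical inputs and
#' seed reproduce the result exactly.
#'
#' @param pool A `species_pool` (e.g. [generate_metabolic_pool()]).
#' @param env An [env_clim()]; derived predictors are added when missing.
#' @param effort An [effort_model()]; defaults to the biased model.
#' @param n_samples Number of sampling events for [sample_occurrences()].
#' @param candidates Candidate predictors for the member sets.
#' @param ranked Rank candidates per species with [rank_predictors()]
#'   before set selection (default `FALSE`: the candidate list itself is
#'   the selection pool, appropriate when it is within the top-10 pool
#'   size anyway).
#' @param algorithm Member algorithm for all species (default `"gam"`).
#' @param target_mode Target-group mode (default `"total"`).
#' @param ratio Background-to-presence ratio (default 10).
#' @param min_presences Minimum presences to model a species (default 24,
#'   a presence-to-predictor ratio of 6 with 4-predictor members).
#' @param tss_min Member retention threshold (default 0.35).
#' @param n_sets,set_size Predictor-set plan shape (default 5 x 4).
#' @param rf_trees Forest size for `"rf"` members.
#' @param seed Integer master seed.
#' @param keep_set_maps Keep per-set binary maps (needed for
#'   [monte_carlo_diversity()]).
#' @param compute_turnover Also compute the turnover map.
#' @param occurrence_args Extra arguments passed to [sample_occurrences()].
#' @return A list of class `sdm_pipeline`: `records` (cleaned),
#'   `presences`, `fits`, `ensembles`, `richness` (a [stack_richness()]
#'   result), `turnover` (or `NULL`), `annual_T` (open-ocean annual-mean
#'   temperature matrix), `ocean` (open-ocean cell mask), `species_status`
#'   (per-species modelling outcome), `reports` (filter reports), `env`,
#'   `plans`.
#' @export
run_sdm_pipeline <- function(pool, env, effort = NULL, n_samples,
                             candidates = c("T", "S", "PAR", "wind",
                                            "logChl", "logNO3", "logMLD",
                                            "Nstar", "Sistar", "MLPAR",
                                            "dTdt", "dMLDdt"),
                             ranked = FALSE,
                             algorithm = c("gam", "glm", "rf"),
                             target_mode = c("total", "group-specific"),
                             ratio = 10, min_presences = 24,
                             tss_min = 0.35, n_sets = 5, set_size = 4,
                             rf_trees = 4000, seed = 1,
                             keep_set_maps = FALSE,
                             compute_turnover = FALSE,
                             occurrence_args = list()) {
  algorithm <- match.arg(algorithm)
  target_mode <- match.arg(target_mode)
  stopifnot(inherits(pool, "species_pool"), inherits(env, "env_clim"))

  if (!all(candidates %in% env_vars(env)))
    env <- derive_predictors(env)
  missing_cand <- setdiff(candidates, env_vars(env))
  if (length(missing_cand))
    stop("run_sdm_pipeline: unknown candidate predictors: ",
         paste(missing_cand, collapse = ", "))
  if (is.null(effort))
    effort <- effort_model(env$grid, "biased", env = env,
                           seed = derive_seed(seed, 1))

  records <- do.call(sample_occurrences,
                     c(list(pool = pool, env = env, effort = effort,
                            n_samples = n_samples,
                            seed = derive_seed(seed, 2)),
                       occurrence_args))
  filt <- filter_records(records, env)
  mask <- apply_open_ocean_mask(filt$records, env)
  records <- mask$records
  presences <- bin_presences(records, env$grid)

  counts <- presence_counts(presences)
  modelable <- names(counts)[counts >= min_presences]
  status <- data.frame(species_id = pool$species_id,
                       n_presences = as.integer(counts[pool$species_id]),
                       stringsAsFactors = FALSE)
  status$n_presences[is.na(status$n_presences)] <- 0L
  status$modeled <- status$species_id %in% modelable
  status$n_retained <- 0L

  group_map <- stats::setNames(pool$taxon, pool$species_id)
  groups <- build_target_group(presences, group_map, mode = target_mode)
  cmat <- predictor_correlations(env, candidates)

  fits <- list()
  plans <- list()
  ensembles <- list()
  status$failed <- FALSE
  for (sp in modelable) {
    sp_seed <- derive_seed(seed, 10 + match(sp, pool$species_id))
    fit <- tryCatch({
      strata <- stratify(groups[[sp]], env)
      bg <- suppressWarnings(
        sample_background(sp, presences, strata, ratio = ratio,
                          seed = sp_seed))
      plan <- if (ranked) {
        train_all <- sdm_training_data(sp, presences, bg, env, candidates)
        rk <- rank_predictors(train_all, candidates,
                              min_presences = min_presences,
                              seed = sp_seed)
        select_predictor_sets(rk, cmat, n_sets = n_sets,
                              set_size = set_size, seed = sp_seed)
      } else {
        select_predictor_sets(NULL, cmat, candidates = candidates,
                              n_sets = n_sets, set_size = set_size,
                              seed = sp_seed)
      }
      fit_species_sdm(sp, presences, bg, env, plan,
                      algorithm = algorithm, tss_min = tss_min,
                      rf_trees = rf_trees, seed = sp_seed)
    }, error = function(e) {
      warning(sprintf("run_sdm_pipeline: species %s failed: %s", sp,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(fit)) {
      status$failed[status$species_id == sp] <- TRUE
      next
    }
    if (!keep_set_maps) {
      keep <- fit
      keep$set_maps <- NULL
      fits[[sp]] <- keep
    } else fits[[sp]] <- fit
    plans[[sp]] <- plan
    status$n_retained[status$species_id == sp] <-
      if (is.null(fit$ensemble)) 0L else fit$ensemble$n_retained
    if (!is.null(fit$ensemble)) ensembles[[sp]] <- fit$ensemble
  }
  if (length(ensembles) == 0)
    stop("run_sdm_pipeline: no species retained any member model")

  ocean <- open_ocean_cells(env)
  richness <- stack_richness(ensembles)
  richness$annual[!ocean] <- NA_real_
  for (m in 1:12) richness$monthly[m, , ][!ocean] <- NA_real_
  turnover <- if (compute_turnover) {
    tv <- turnover_map(ensembles)
    tv$mean[!ocean] <- NA_real_
    tv
  } else NULL

  annual_T <- apply(env_field(env, "T"), c(2, 3), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  annual_T[!ocean] <- NA_real_

  structure(list(records = records, presences = presences, fits = fits,
                 ensembles = ensembles, richness = richness,
                 turnover = turnover, annual_T = annual_T, ocean = ocean,
                 species_status = status,
                 reports = list(filter = filt$report, mask = mask$report),
                 env = env, plans = plans, seed = seed,
                 algorithm = algorithm),
            class = "sdm_pipeline")
}

#' @export
print.sdm_pipeline <- function(x, ...) {
  st <- x$species_status
  cat(sprintf(
    "<sdm_pipeline> %s: %d species in pool, %d modeled, %d with ensembles\n",
    toupper(x$algorithm), nrow(st), sum(st$modeled),
    sum(st$n_retained > 0)))
  cat(sprintf("  %d cleaned records, %d gridded presences\n",
              nrow(x$records), nrow(x$presences)))
  invisible(x)
}

#' Metabolic slope recovered by a pipeline run
#'
#' Regresses the log annual-mean stacked richness on inverse thermal
#' energy over all open-ocean cells of a pipeline result and returns the
#' global regression row -- the quantity compared against the generative
#' activation energy in recovery experiments.
#'
#' @param pipeline A [run_sdm_pipeline()] result.
#' @param breakpoints Passed to [fit_thermal_regimes()].
#' @return The `regime_fit` data frame, with the global slope in
#'   `attr(, "global_slope")`.
#' @export
pipeline_metabolic_fit <- function(pipeline, breakpoints = c(11, 19)) {
  stopifnot(inherits(pipeline, "sdm_pipeline"))
  fit <- fit_thermal_regimes(as.vector(pipeline$richness$annual),
                             as.vector(pipeline$annual_T),
                             breakpoints = breakpoints)
  structure(fit, global_slope = fit$slope[fit$regime == "global"])
}

#' Presence-to-predictor ratio of the modelling threshold
#'
#' Member models use `set_size` predictors, so requiring at least
#' `min_presences` presences fixes the minimum number of presences per
#' predictor.  With the defaults (24 presences, 4 predictors) the ratio is
#' 6, the conventional lower bound for stable niche fits.
#'
#' @param min_presences Presence threshold (default 24).
#' @param set_size Predictors per member model (default 4).
#' @return The ratio `min_presences / set_size`.
#' @export
presence_predictor_ratio <- function(min_presences = 24, set_size = 4) {
  stopifnot(set_size >= 1)
  min_presences / set_size
}
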