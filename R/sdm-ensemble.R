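#' Global Spearman correlations between candidate predictors
#'
#' Computed from the predictor data at global monthly 1-degree resolution
#' (pairwise-complete cells); used to keep strongly collinear predictors
#' out of the same member model.
#'
#' @param env An [env_clim()].
#' @param candidates Predictor names.
#' @return A symmetric correlation matrix.
#' @export
predictor_correlations <- function(env, candidates = default_candidates()) {
  candidates <- intersect(candidates, env_vars(env))
  mat <- vapply(candidates, function(v) as.vector(env_field(env, v)),
                numeric(12 * env$grid$n_lat * env$grid$n_lon))
  stats::cor(mat, method = "spearman", use = "pairwise.complete.obs")
}

#' Randomised low-correlation predictor sets for the ensemble members
#'
#' Builds `n_sets` sets of `set_size` predictors per species.  Predictors
#' are drawn at random, without replacement within a set, from the
#' species' `top_n` best-ranked candidates; a draw is admissible only when
#' its global Spearman correlation with every predictor already in the set
#' is at most `corr_max` in magnitude, and a predictor may appear in at
#' most `reuse_max` of the sets.  When the top-ranked pool cannot complete
#' a set under these constraints, lower-ranked candidates are admitted.
#' The whole plan is restarted with a fresh shuffle when a dead end is
#' reached; an error is raised only when no valid plan exists after
#' `max_restarts` restarts.
#'
#' When `ranking` is `NULL` the candidate vector itself defines the pool
#' (all candidates treated as top-ranked, fallback in the given order) --
#' useful when the candidate list is already at most `top_n` long, where
#' the ranking cannot change the pool.
#'
#' @param ranking A [rank_predictors()] result, or `NULL`.
#' @param cor_matrix Correlation matrix from [predictor_correlations()].
#' @param candidates Candidate names (required when `ranking` is `NULL`;
#'   otherwise taken from the ranking).
#' @param n_sets,set_size Plan shape (default 5 sets of 4).
#' @param corr_max Maximum absolute pairwise correlation within a set.
#' @param reuse_max Maximum number of sets a predictor may appear in.
#' @param top_n Size of the preferred pool (default 10).
#' @param seed Integer seed.
#' @param max_restarts Restart budget before giving up.
#' @return A list of class `predictor_set_plan` with `n_sets` character
#'   vectors of length `set_size`.
#' @export
select_predictor_sets <- function(ranking = NULL, cor_matrix,
                                  candidates = NULL, n_sets = 5,
                                  set_size = 4, corr_max = 0.7,
                                  reuse_max = 2, top_n = 10, seed = 1,
                                  max_restarts = 100) {
  if (!is.null(ranking)) {
    candidates <- ranking$predictor
  }
  if (is.null(candidates) || length(candidates) < set_size)
    stop("select_predictor_sets: need at least set_size candidates")
  if (length(candidates) * reuse_max < n_sets * set_size)
    stop(sprintf(
      "select_predictor_sets: %d candidates reused at most %d times cannot fill %d x %d slots",
      length(candidates), reuse_max, n_sets, set_size))
  missing_cor <- setdiff(candidates, rownames(cor_matrix))
  if (length(missing_cor))
    stop("select_predictor_sets: correlation matrix lacks: ",
         paste(missing_cor, collapse = ", "))
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  ## without a ranking there is no top-n pool: all candidates are peers
  n_pref <- if (is.null(ranking)) length(candidates)
  else min(top_n, length(candidates))
  preferred <- candidates[seq_len(n_pref)]
  fallback <- setdiff(candidates, preferred)

  compatible <- function(v, chosen) {
    if (length(chosen) == 0) return(TRUE)
    r <- cor_matrix[v, chosen]
    all(is.na(r) | abs(r) <= corr_max)
  }

  for (restart in seq_len(max_restarts)) {
    reuse <- stats::setNames(integer(length(candidates)), candidates)
    plan <- vector("list", n_sets)
    failed <- FALSE
    for (s in seq_len(n_sets)) {
      ## prefer the top-ranked pool with fallback appended in rank order;
      ## in the second half of the restart budget the preference is
      ## relaxed (whole pool shuffled) so tight constraint graphs where
      ## early sets must already dip into the fallback remain solvable
      order_pool <- if (restart <= max_restarts / 2)
        c(sample(preferred), fallback)
      else sample(candidates)
      chosen <- character(0)
      for (v in order_pool) {
        if (length(chosen) == set_size) break
        if (reuse[[v]] >= reuse_max) next
        if (!compatible(v, chosen)) next
        chosen <- c(chosen, v)
      }
      if (length(chosen) < set_size) { failed <- TRUE; break }
      reuse[chosen] <- reuse[chosen] + 1
      plan[[s]] <- chosen
    }
    if (!failed)
      return(structure(plan, class = "predictor_set_plan"))
  }
  stop("select_predictor_sets: constraints unsatisfiable for this species")
}

#' Assemble presence/background training data for one species
#'
#' @param species_id Focal species.
#' @param presences A [bin_presences()] result.
#' @param background A [sample_background()] result for the species.
#' @param env An [env_clim()] (typically after [derive_predictors()]).
#' @param vars Predictor columns to attach.
#' @return Data frame with `label` (1 = presence, 0 = background), the
#'   monthly-cell keys and one column per predictor.
#' @export
sdm_training_data <- function(species_id, presences, background, env,
                              vars) {
  pres <- presences[presences$species_id == species_id,
                    c("month", "lat_idx", "lon_idx")]
  bg <- background[, c("month", "lat_idx", "lon_idx")]
  keys <- rbind(pres, bg)
  out <- cbind(data.frame(label = rep(c(1, 0), c(nrow(pres), nrow(bg)))),
               keys, env_matchup(env, keys, vars))
  rownames(out) <- NULL
  out
}

#' Fit, evaluate and project the SDM ensemble of one species
#'
#' One member model is fitted per predictor set in the plan, evaluated by
#' 4-fold split-sample cross-validation, retained when its cross-validated
#' TSS reaches `tss_min`, binarised at its full-data max-TSS threshold and
#' projected onto the monthly climatology.  The ensemble is the per-cell
#' mean of the retained members' binary projections, a value in `[0, 1]`
#' equal to the fraction of retained members projecting presence.
#'
#' @param species_id Focal species.
#' @param presences,background,env As in [sdm_training_data()].
#' @param plan A [select_predictor_sets()] plan.
#' @param algorithm `"glm"`, `"gam"` or `"rf"` for all members.
#' @param tss_min Member retention threshold (default 0.35).
#' @param folds Cross-validation parts (default 4).
#' @param rf_trees Forest size (default 4000).
#' @param seed Integer seed.
#' @param keep_models Keep fitted member objects (default `FALSE`: only
#'   projections and evaluation metadata are retained, which keeps large
#'   multi-species runs small in memory).
#' @return A list of class `species_sdm`: `species_id`, `members` (metadata
#'   per member: predictors, cv TSS, threshold, retained), `ensemble` (an
#'   `ensemble_projection`, or `NULL` when no member is retained) and
#'   `set_maps` (per-member binary arrays, retained members only).
#' @export
fit_species_sdm <- function(species_id, presences, background, env, plan,
                            algorithm = c("gam", "glm", "rf"),
                            tss_min = 0.35, folds = 4, rf_trees = 4000,
                            seed = 1, keep_models = FALSE) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(plan, "predictor_set_plan"))
  vars <- unique(unlist(plan))
  train <- sdm_training_data(species_id, presences, background, env, vars)

  members <- vector("list", length(plan))
  set_maps <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    m <- evaluate_member(train, algorithm, plan[[i]], tss_min = tss_min,
                         folds = folds, rf_trees = rf_trees,
                         seed = derive_seed(seed, i))
    if (!is.null(m)) {
      if (isTRUE(m$retained))
        set_maps[[i]] <- project_member(m, env)
      if (!keep_models) m$model <- NULL
      members[[i]] <- m
    }
  }
  retained <- which(vapply(members, function(m)
    !is.null(m) && isTRUE(m$retained), logical(1)))
  ensemble <- if (length(retained)) {
    vals <- Reduce(`+`, set_maps[retained]) / length(retained)
    structure(list(species_id = species_id, values = vals,
                   n_retained = length(retained)),
              class = "ensemble_projection")
  } else NULL
  structure(list(species_id = species_id, members = members,
                 ensemble = ensemble,
                 set_maps = set_maps),
            class = "species_sdm")
}

#' Average retained member projections into an ensemble
#'
#' @param members A list of evaluated `sdm_member` objects for one species.
#' @param env An [env_clim()].
#' @param tss_min Retention threshold applied to the members'
#'   cross-validated TSS (default 0.35).
#' @param species_id Identifier stored in the result.
#' @return An `ensemble_projection` (per monthly cell: the mean of the
#'   retained members' 0/1 projections), or `NULL` with a message when no
#'   member passes retention.
#' @export
build_ensemble <- function(members, env, tss_min = 0.35,
                           species_id = NA_character_) {
  members <- Filter(Negate(is.null), members)
  retained <- Filter(function(m) is.finite(m$cv_tss) && m$cv_tss >= tss_min,
                     members)
  if (length(retained) == 0) {
    message("build_ensemble: no member reaches TSS >= ", tss_min,
            "; species excluded")
    return(NULL)
  }
  maps <- lapply(retained, project_member, env = env)
  vals <- Reduce(`+`, maps) / length(maps)
  structure(list(species_id = species_id, values = vals,
                 n_retained = length(retained)),
            class = "ensemble_projection")
}

#' @export
print.ensemble_projection <- function(x, ...) {
  cat(sprintf("<ensemble_projection> %s: %d retained member(s), mean %.3f\n",
              x$species_id, x$n_retained, mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Write a member-model registry as CSV
#'
#' One row per member: species, algorithm, predictors, cross-validated
#' TSS, threshold and retention flag.
#'
#' @param fits A list of `species_sdm` objects.
#' @param path File path.
#' @export
write_member_registry <- function(fits, path) {
  rows <- do.call(rbind, lapply(fits, function(f) {
    do.call(rbind, lapply(seq_along(f$members), function(i) {
      m <- f$members[[i]]
      if (is.null(m)) return(NULL)
      data.frame(species_id = f$species_id, set = i,
                 algorithm = m$algorithm,
                 predictors = paste(m$predictors, collapse = "|"),
                 cv_tss = m$cv_tss, threshold = m$threshold,
                 retained = isTRUE(m$retained),
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
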