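#' Derive secondary predictor fields
#'
#' Augments a climatology with the derived predictors used for niche
#' modelling:
#'
#' * `Nstar` -- nitrate in excess of the Redfield ratio,
#'   `NO3 - 16 * PO4` (uM); decorrelates the nitrogen signal from
#'   temperature.
#' * `Sistar` -- the ratio `SiOH4 / NO3` (dimensionless), missing where
#'   `NO3 = 0`; relevant for diatoms.
#' * `MLPAR` -- mean photosynthetically active radiation over the mixed
#'   layer, `PAR * (1 - exp(-kd * MLD)) / (kd * MLD)` with the
#'   chlorophyll-dependent attenuation
#'   `kd = 0.04 + 0.0088 * Chl + 0.054 * Chl^(2/3)` per metre.
#' * `dTdt`, `dNO3dt`, `dPO4dt`, `dSidt`, `dMLDdt` -- temporal trends as
#'   the centred mean difference of each month with its neighbours,
#'   `(X[m+1] - X[m-1]) / 2`, with circular December-January wrap (so the
#'   trends of any cell sum to zero over the year).
#' * `logMLD`, `logChl`, `logNO3`, `logPO4`, `logSiOH4` -- base-10
#'   logarithms, missing where the source is not positive.
#'
#' Derived fields whose source variables are absent are skipped with a
#' warning.
#'
#' @param env An [env_clim()].
#' @param attenuation Function `(Chl) -> kd` (per metre) used by `MLPAR`;
#'   replaceable to explore other optical models.
#' @return The augmented [env_clim()].
#' @export
derive_predictors <- function(env,
                              attenuation = function(chl)
                                0.04 + 0.0088 * chl + 0.054 * chl^(2 / 3)) {
  stopifnot(inherits(env, "env_clim"))
  f <- env$fields
  have <- function(...) all(c(...) %in% names(f))
  want_warn <- function(what, need)
    warning(sprintf("derive_predictors: skipping %s (needs %s)",
                    what, paste(need, collapse = ", ")))

  if (have("NO3", "PO4")) f$Nstar <- f$NO3 - 16 * f$PO4
  else want_warn("Nstar", c("NO3", "PO4"))

  if (have("SiOH4", "NO3")) {
    s <- f$SiOH4 / f$NO3
    s[!is.na(f$NO3) & f$NO3 == 0] <- NA_real_
    f$Sistar <- s
  } else want_warn("Sistar", c("SiOH4", "NO3"))

  if (have("PAR", "MLD", "Chl")) {
    kd <- attenuation(f$Chl)
    f$MLPAR <- f$PAR * (1 - exp(-kd * f$MLD)) / (kd * f$MLD)
  } else want_warn("MLPAR", c("PAR", "MLD", "Chl"))

  trend <- function(a) {
    up <- a[c(2:12, 1), , , drop = FALSE]
    dn <- a[c(12, 1:11), , , drop = FALSE]
    (up - dn) / 2
  }
  for (src in c(Tv = "T", NO3 = "NO3", PO4 = "PO4", Si = "SiOH4",
                MLD = "MLD")) {
    nm <- paste0("d", sub("SiOH4", "Si", src), "dt")
    if (src %in% names(f)) f[[nm]] <- trend(f[[src]])
    else want_warn(nm, src)
  }

  for (src in c("MLD", "Chl", "NO3", "PO4", "SiOH4")) {
    nm <- paste0("log", src)
    if (src %in% names(f)) {
      v <- f[[src]]
      v[!is.na(v) & v <= 0] <- NA_real_
      f[[nm]] <- log10(v)
    } else want_warn(nm, src)
  }

  env_clim(env$grid, f)
}

#' Default candidate predictor list
#'
#' The raw variables plus the derived fields of [derive_predictors()] that
#' enter single-predictor skill tests by default (bathymetry is excluded as
#' it is not a niche axis).
#'
#' @return Character vector of predictor names.
#' @export
default_candidates <- function() {
  c("T", "S", "NO3", "PO4", "SiOH4", "MLD", "PAR", "Chl", "wind", "pCO2",
    "Nstar", "Sistar", "MLPAR", "dTdt", "dNO3dt", "dPO4dt", "dSidt",
    "dMLDdt", "logMLD", "logChl", "logNO3", "logPO4", "logSiOH4")
}

#' Adjusted D-squared
#'
#' Deviance-based explained variation, penalised for model size:
#' `D2 = (null - residual) / null` and
#' `adjD2 = 1 - ((n - 1) / (n - p)) * (1 - D2)`.
#'
#' @param null_deviance Null deviance (> 0).
#' @param residual_deviance Residual deviance.
#' @param n Number of observations.
#' @param p Number of parameters (must be < n).
#' @return The adjusted D-squared (at most 1; can be negative for useless
#'   models).
#' @export
adjusted_d2 <- function(null_deviance, residual_deviance, n, p) {
  stopifnot(null_deviance > 0)
  if (n <= p) stop("adjusted_d2: undefined for n <= p")
  d2 <- (null_deviance - residual_deviance) / null_deviance
  1 - ((n - 1) / (n - p)) * (1 - d2)
}

#' Rank candidate predictors by single-predictor model skill
#'
#' Fits, for each candidate, three single-predictor models of presence (1)
#' versus background (0): a GLM with linear and quadratic terms, a GAM with
#' a five-basis-dimension smooth, and a random forest.  GLM and GAM are
#' scored by adjusted D-squared; the forest by its out-of-bag error,
#' converted to the skill `1 - OOB` so all three axes rank descending.
#' Presences keep weight one and each background row is weighted by the
#' presence/background ratio so the classes carry equal total weight in GLM
#' and GAM.  Per-algorithm ranks (ties get average rank) are averaged into
#' the mean rank that orders the final ranking; candidates whose fit fails
#' receive the worst rank for that algorithm with a warning.
#'
#' @param data Data frame with a 0/1 `label` column and one column per
#'   candidate predictor (rows = presence and background matchups of one
#'   species).
#' @param candidates Character vector of predictor columns to test.
#' @param min_presences Minimum presences required (default 24).
#' @param rf_trees Trees for the single-predictor forest (default 500).
#' @param seed Integer seed (forest randomness).
#' @return A data frame of class `predictor_ranking`, ordered by `mean_rank`,
#'   with columns `predictor`, `d2_glm`, `d2_gam`, `oob_rf`, `rank_glm`,
#'   `rank_gam`, `rank_rf`, `mean_rank`.
#' @export
rank_predictors <- function(data, candidates, min_presences = 24,
                            rf_trees = 500, seed = 1) {
  stopifnot(all(candidates %in% names(data)), "label" %in% names(data))
  n_pres <- sum(data$label == 1)
  if (n_pres < min_presences)
    stop(sprintf("rank_predictors: %d presences < required %d",
                 n_pres, min_presences))
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  score <- function(cand) {
    d <- data[!is.na(data[[cand]]), c("label", cand)]
    names(d) <- c("y", "x")
    np <- sum(d$y == 1); nb <- sum(d$y == 0)
    if (np < 2 || nb < 2) return(c(NA, NA, NA))
    w <- ifelse(d$y == 1, 1, np / nb)
    g <- tryCatch(suppressWarnings(
      stats::glm(y ~ x + I(x^2), family = stats::binomial, data = d,
                 weights = w)),
      error = function(e) NULL)
    d2g <- if (is.null(g)) NA_real_ else
      adjusted_d2(g$null.deviance, g$deviance, nrow(d),
                  length(stats::coef(g)))
    a <- tryCatch(suppressWarnings(
      mgcv::gam(y ~ s(x, k = 5), family = stats::binomial, data = d,
                weights = w)),
      error = function(e) NULL)
    d2a <- if (is.null(a)) NA_real_ else
      adjusted_d2(a$null.deviance, a$deviance, nrow(d),
                  sum(a$edf) + 1)
    ## a forest on a single constant covariate cannot split and is skipped
    r <- if (length(unique(d$x)) < 2) NULL else tryCatch(suppressWarnings(
      randomForest::randomForest(x = d[, "x", drop = FALSE],
                                 y = factor(d$y, levels = c(0, 1)),
                                 ntree = rf_trees,
                                 sampsize = c(`0` = min(np, nb),
                                              `1` = min(np, nb)),
                                 strata = factor(d$y, levels = c(0, 1)))),
      error = function(e) NULL)
    oob <- if (is.null(r)) NA_real_ else
      unname(r$err.rate[rf_trees, "OOB"])
    c(d2g, d2a, oob)
  }

  sc <- t(vapply(candidates, score, numeric(3)))
  if (any(is.na(sc)))
    warning("rank_predictors: some single-predictor fits failed; ",
            "they receive the worst rank")
  worst_rank <- function(skill) {
    ## descending skill; NA (failed) -> worst
    r <- rank(-skill, ties.method = "average", na.last = "keep")
    r[is.na(r)] <- length(skill)
    r
  }
  out <- data.frame(predictor = candidates,
                    d2_glm = sc[, 1], d2_gam = sc[, 2],
                    oob_rf = sc[, 3],
                    rank_glm = worst_rank(sc[, 1]),
                    rank_gam = worst_rank(sc[, 2]),
                    rank_rf = worst_rank(1 - sc[, 3]),
                    stringsAsFactors = FALSE)
  out$mean_rank <- rowMeans(out[, c("rank_glm", "rank_gam", "rank_rf")])
  out <- out[order(out$mean_rank, out$predictor), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("predictor_ranking", "data.frame"))
}
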