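#' Configure virtual species niches
#'
#' Virtual species carry unimodal (Gaussian) response curves: suitability for
#' predictor `x` is `exp(-(x - opt)^2 / (2 * breadth^2))`, responses multiply
#' across predictors, and the product is scaled by the species' maximum
#' occurrence probability.  Optima and breadths are drawn uniformly from the
#' configured ranges.
#'
#' @param predictors Named list; one entry per environmental variable, each a
#'   list with `opt = c(lo, hi)` and `breadth = c(lo, hi)` giving the uniform
#'   draw ranges for the optimum and the (strictly positive) niche breadth.
#' @param max_prob Range for the uniform draw of the species' maximum
#'   occurrence probability (detectability ceiling), in `(0, 1]`.
#' @param taxa Character vector of taxon labels cycled over species; used by
#'   the target-group machinery downstream.
#' @return A list of class `niche_config`.
#' @export
niche_config <- function(predictors = list(T = list(opt = c(0, 30),
                                                    breadth = c(3, 8))),
                         max_prob = c(0.6, 1),
                         taxa = c("Bacillariophyceae", "Dinoflagellata",
                                  "Haptophyta", "Chlorophyta")) {
  stopifnot(is.list(predictors), length(predictors) >= 1,
            !is.null(names(predictors)),
            length(max_prob) == 2, max_prob[1] > 0, max_prob[2] <= 1)
  for (nm in names(predictors)) {
    p <- predictors[[nm]]
    if (is.null(p$opt) || is.null(p$breadth) || length(p$opt) != 2 ||
        length(p$breadth) != 2 || any(p$breadth <= 0))
      stop(sprintf(
        "niche_config: predictor '%s' needs opt = c(lo, hi) and strictly positive breadth = c(lo, hi)",
        nm))
  }
  structure(list(predictors = predictors, max_prob = max_prob, taxa = taxa),
            class = "niche_config")
}

#' Generate a pool of virtual species with known niches
#'
#' @param n_species Number of species (>= 1).
#' @param config A [niche_config()].
#' @param seed Integer seed; identical `(config, seed)` reproduce the pool
#'   exactly.
#' @return A data frame of class `species_pool` with one row per species:
#'   `species_id`, `taxon`, `max_prob`, and `opt_<var>` / `breadth_<var>`
#'   columns for each configured predictor.  The niche variable names are
#'   kept in `attr(, "niche_vars")`.
#' @export
generate_species_pool <- function(n_species, config = niche_config(),
                                  seed = 1) {
  stopifnot(n_species >= 1, inherits(config, "niche_config"))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  pool <- data.frame(
    species_id = sprintf("sp%04d", seq_len(n_species)),
    taxon = rep(config$taxa, length.out = n_species),
    max_prob = stats::runif(n_species, config$max_prob[1],
                            config$max_prob[2]),
    stringsAsFactors = FALSE
  )
  for (nm in names(config$predictors)) {
    p <- config$predictors[[nm]]
    pool[[paste0("opt_", nm)]] <- stats::runif(n_species, p$opt[1], p$opt[2])
    pool[[paste0("breadth_", nm)]] <-
      stats::runif(n_species, p$breadth[1], p$breadth[2])
  }
  structure(pool, niche_vars = names(config$predictors),
            class = c("species_pool", "data.frame"))
}

#' True suitability of a virtual species over the climatology
#'
#' @param species One row of a `species_pool`.
#' @param env An [env_clim()].
#' @return A `(12, n_lat, n_lon)` array of suitabilities in `[0, 1]`, `NA`
#'   where any niche variable is missing.
#' @export
species_suitability <- function(species, env) {
  vars <- attr(species, "niche_vars") %||%
    sub("^opt_", "", grep("^opt_", names(species), value = TRUE))
  suit <- array(species$max_prob[1],
                dim = c(12L, env$grid$n_lat, env$grid$n_lon))
  for (v in vars) {
    x <- env_field(env, v)
    suit <- suit * exp(-(x - species[[paste0("opt_", v)]][1])^2 /
                         (2 * species[[paste0("breadth_", v)]][1]^2))
  }
  suit
}

## Suitability of every species in `pool` at the monthly cells given by
## linear index `idx` into the climatology arrays; returns (length(idx),
## n_species) matrix.  Hot path of the occurrence sampler.
pool_suitability_at <- function(pool, env, idx) {
  vars <- attr(pool, "niche_vars")
  n <- nrow(pool)
  out <- matrix(rep(pool$max_prob, each = length(idx)), length(idx), n)
  for (v in vars) {
    x <- env$fields[[v]][idx]
    opt <- pool[[paste0("opt_", v)]]
    br <- pool[[paste0("breadth_", v)]]
    out <- out * exp(-sweep(outer(x, opt, "-"), 2, br, "/")^2 / 2)
  }
  out
}

#' Generate a species pool consistent with metabolic theory
#'
#' Builds `n_species` thermal specialists whose ranges are arranged so the
#' expected number of species whose range covers temperature `T` follows
#' `ln S = c - E / (k T)` across the climatology's temperature span, with
#' `E` the activation energy in eV and `k` Boltzmann's constant
#' (8.617e-5 eV/K).  Range midpoints are placed by stratified
#' inverse-transform sampling from a density proportional to
#' `exp(-E / (k m))` over the span widened by half a range width on either
#' side (so the log-linear law holds without edge truncation); all species
#' share a fixed thermal range width, and a species' range is the interval
#' where its Gaussian response exceeds half its maximum.
#'
#' @param n_species Number of species; small pools resolve the gradient
#'   poorly and trigger a warning below 50.
#' @param activation_energy Target slope magnitude `E` in eV (>= 0).
#' @param env An [env_clim()] providing the temperature field.
#' @param seed Integer seed.
#' @param range_width Thermal range width in degrees C shared by all species.
#' @param max_prob Maximum occurrence probability shared by all species.
#' @param taxa Taxon labels cycled over species.
#' @return A `species_pool` with extra attributes: `activation_energy`,
#'   `range_width`, and `intercept` -- the realised `c` of the expected
#'   log-overlap law, obtained by regressing the expected overlap count on
#'   inverse thermal energy over the climatology's temperature values.
#' @export
generate_metabolic_pool <- function(n_species, activation_energy, env,
                                    seed = 1, range_width = 14,
                                    max_prob = 0.7,
                                    taxa = c("Bacillariophyceae",
                                             "Dinoflagellata",
                                             "Haptophyta", "Chlorophyta")) {
  stopifnot(n_species >= 1, activation_energy >= 0, range_width > 0,
            inherits(env, "env_clim"))
  if (n_species < 50)
    warning("generate_metabolic_pool: fewer than 50 species resolves the ",
            "thermal gradient poorly")
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  Tv <- env_field(env, "T")
  Tv <- Tv[!is.na(Tv)]
  t_lo <- min(Tv); t_hi <- max(Tv)
  w <- range_width
  mg <- seq(t_lo - w / 2, t_hi + w / 2, length.out = 4096)
  dens <- exp(-activation_energy / (boltzmann_k() * (mg + 273.15)))
  cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]

  ## stratified inverse-transform draw of midpoints (low-variance placement)
  u <- (seq_len(n_species) - stats::runif(n_species)) / n_species
  mids <- stats::approx(cdf, mg, xout = u, ties = "ordered")$y
  mids <- sample(mids)   # decouple species order from thermal order

  breadth <- (w / 2) / sqrt(2 * log(2))  # half-max response at +/- w/2
  pool <- data.frame(
    species_id = sprintf("sp%04d", seq_len(n_species)),
    taxon = rep(taxa, length.out = n_species),
    max_prob = rep(max_prob, n_species),
    opt_T = mids,
    breadth_T = rep(breadth, n_species),
    stringsAsFactors = FALSE
  )
  pool <- structure(pool, niche_vars = "T",
                    class = c("species_pool", "data.frame"))

  ## realised intercept of the expected log-overlap law on this grid
  cdf_at <- function(x) stats::approx(mg, cdf, xout = x, rule = 2,
                                      ties = "ordered")$y
  t_eval <- seq(t_lo, t_hi, length.out = 256)
  s_exp <- n_species * (cdf_at(t_eval + w / 2) - cdf_at(t_eval - w / 2))
  fit <- stats::lm(log(s_exp) ~ I(1 / (boltzmann_k() * (t_eval + 273.15))))
  attr(pool, "activation_energy") <- activation_energy
  attr(pool, "range_width") <- w
  attr(pool, "intercept") <- unname(stats::coef(fit)[1])
  attr(pool, "expected_slope") <- unname(stats::coef(fit)[2])
  pool
}

#' Boltzmann's constant in eV per kelvin
#' @return The scalar 8.617e-5.
#' @export
boltzmann_k <- function() 8.617e-5

#' Thermal ranges and true overlap counts of a virtual pool
#'
#' A species' thermal range is where its response exceeds `level` times its
#' maximum; for Gaussian responses that is `opt +/- breadth *
#' sqrt(-2 log(level))`.  `true_overlap` counts, for each temperature, the
#' species whose range covers it -- the ground truth for richness recovery.
#'
#' @param pool A `species_pool` with a thermal niche (`opt_T`, `breadth_T`).
#' @param level Relative response level defining the range edge (default
#'   half-maximum).
#' @return `species_ranges`: data frame `species_id`, `t_min`, `t_max`.
#' @export
species_ranges <- function(pool, level = 0.5) {
  stopifnot(all(c("opt_T", "breadth_T") %in% names(pool)),
            level > 0, level < 1)
  half <- pool$breadth_T * sqrt(-2 * log(level))
  data.frame(species_id = pool$species_id,
             t_min = pool$opt_T - half, t_max = pool$opt_T + half,
             stringsAsFactors = FALSE)
}

#' @rdname species_ranges
#' @param temperatures Numeric vector of temperatures (degrees C).
#' @export
true_overlap <- function(pool, temperatures, level = 0.5) {
  r <- species_ranges(pool, level)
  vapply(temperatures,
         function(t) sum(r$t_min <= t & t <= r$t_max), numeric(1))
}
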