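## Internal helpers shared across modules.

## Seed handling: every stochastic operation takes an integer seed and
## restores the caller's RNG state on exit, so pipelines are reproducible
## without clobbering the session RNG.
local_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

## Derive a stage/species seed from a master seed, kept within 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) %% 100003L
}

## Largest-remainder apportionment of `total` into quotas proportional to
## `weights` (nonnegative, not all zero).  Realised quotas are integers and
## sum exactly to `total`.
largest_remainder <- function(weights, total) {
  stopifnot(all(weights >= 0), total >= 0)
  if (total == 0 || sum(weights) == 0)
    return(integer(length(weights)))
  raw <- total * weights / sum(weights)
  base <- floor(raw)
  left <- as.integer(round(total - sum(base)))
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

## Key string for monthly cells; used for fast set operations.
key_string <- function(month, lat_idx, lon_idx) {
  paste(month, lat_idx, lon_idx, sep = "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
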