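`%||%` <- function(x, y) if (is.null(x)) y else x

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
## All exported simulation functions take an explicit `seed` and route
## through this, so fixed inputs + seed give byte-identical output without
## clobbering the session RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic per-stage substream: a small offset keeps derived seeds
## within 32-bit integer range.
substream_seed <- function(seed, stream) {
  offsets <- c(genome = 101L, sites = 211L, fragments = 307L, sample = 401L,
               null = 503L, misc = 701L)
  stopifnot(stream %in% names(offsets))
  (as.integer(seed) %% 1500000000L) + offsets[[stream]]
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

## Round half away from zero (base round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)
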