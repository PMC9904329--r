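# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream. seed = NULL leaves the stream untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Round half away from zero (drop-down menus force integer responses;
# base round() is half-to-even which would bias 0.5-valued estimates).
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != round(x)) {
    stop(sprintf("`%s` must be a single non-negative integer", name), call. = FALSE)
  }
}
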