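# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring any pre-existing
# RNG state afterwards so generators never leak global state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Descending fractional (average-tie) ranks: rank 1 = largest value.
frac_rank_desc <- function(x) {
  rank(-x, ties.method = "average")
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count_scalar <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

is_real_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
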