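# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a character key
#'
#' A single master seed streams per-group substreams keyed by label, so adding
#' or removing a group never perturbs another group's draws.  The hash is a
#' plain polynomial rolling hash over the UTF-8 bytes of the key, reduced
#' modulo 2^31 - 1 so the result is always a valid 32-bit R seed.
#'
#' @param seed integer master seed.
#' @param key character scalar (e.g. a group label).
#' @return an integer seed in [0, 2^31 - 2].
#' @keywords internal
sub_seed <- function(seed, key) {
  stopifnot(length(key) == 1L, is.character(key))
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% m
  as.integer(h)
}

# Run an expression under a local RNG state: seeds with `seed`, restores the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Consistent stop() with the calling operation's name.
stop2 <- function(...) stop(..., call. = FALSE)
warn2 <- function(...) warning(..., call. = FALSE)
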