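#' Derive a reproducible sub-stream seed
#'
#' All randomness in morphodyn flows from one user-supplied seed. Independent
#' sub-streams (one per cell, per bootstrap replicate, ...) are derived by a
#' counter-based linear hash so that any sub-stream can be reproduced without
#' consuming random numbers from the others.
#'
#' @param seed integer master seed.
#' @param stream non-negative integer stream counter.
#' @return an integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1L, 0)
#' derive_seed(1L, 1)
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.numeric(stream), length(stream) == 1L, stream >= 0)
  m <- 2147483647 # 2^31 - 1, keeps products within double precision
  x <- (abs(as.numeric(seed)) %% m) * 48271 + as.numeric(stream) * 16807 + 1
  as.integer(x %% (m - 1) + 1)
}

# Run `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
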