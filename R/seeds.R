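#' Derive a per-stage seed from a global seed
#'
#' All randomness in multi-stage runs flows from a single global seed; each
#' stage hashes its name into the stream so stages are decoupled (adding a
#' stage does not shift another stage's draws). The result is always a valid
#' 32-bit seed.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stage))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(paste(stage, collapse = "/"))) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

#' Evaluate an expression under a fixed seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded stages do not disturb surrounding randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
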