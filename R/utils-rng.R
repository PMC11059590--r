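# RNG plumbing shared by all generators.

#' Derive a child seed from a master seed
#'
#' All stochastic functions in glomRPS take an explicit integer seed. When one
#' seed has to drive several independent generators (e.g. one per patient),
#' child seeds are derived with a fixed linear-congruential mix so that the
#' stream consumed by one generator never depends on how much randomness
#' another one used. The result is always in `[1, 2^31 - 2]`.
#'
#' @param seed master integer seed.
#' @param offset non-negative integer distinguishing the child stream.
#' @return an integer seed usable with [set.seed()].
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.numeric(offset), length(offset) == 1L, offset >= 0)
  m <- 2147483647 # 2^31 - 1, Mersenne prime; arithmetic stays in double range
  x <- (abs(seed) %% m) + 1
  x <- (x * 48271) %% m
  x <- (x + (offset %% m) * 16807) %% m
  as.integer((x %% (m - 1)) + 1)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_glom <- function(msg, class) {
  stop(structure(
    class = c(class, "glomRPS_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
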