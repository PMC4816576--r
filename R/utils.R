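#' Derive a child seed from a master seed
#'
#' Deterministically maps a master seed plus one or more integer stream
#' identifiers onto a new seed in `[1, 2^31 - 2]`. Used throughout the
#' pipeline so that every stage (subject simulation, balancing repeat,
#' fold assignment, permutations) has its own reproducible stream.
#'
#' @param seed integer master seed.
#' @param ... integer stream identifiers (e.g. subject index, repeat index).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (x in ids) {
    h <- (h * 48271 + (as.numeric(x) %% m) + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x) && x > 0
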