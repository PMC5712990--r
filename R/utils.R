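## Internal helpers: argument checks and deterministic seed derivation.

stop_invalid <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < min) {
    stop_invalid(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop_invalid(sprintf("`%s` must be a single number in [0, 1]", name))
  }
  as.numeric(x)
}

#' Derive a reproducible child seed from integer components
#'
#' Mixes an arbitrary number of integer components (master seed, graph
#' index, replicate index, stage tag, ...) into a single seed in
#' `[0, 2^31 - 2]`. Used so that every trial and pipeline stage has its own
#' deterministic random stream derived from one master seed. The
#' multiplicative congruential mix keeps all intermediates below 2^53, so
#' the arithmetic is exact in double precision.
#'
#' @param ... integer-valued components.
#' @return A single integer seed.
#' @examples
#' mix_seed(1, 17, 3)
#' @export
mix_seed <- function(...) {
  v <- as.numeric(c(...))
  if (any(!is.finite(v) | v != round(v))) {
    stop_invalid("seed components must be finite integers")
  }
  m <- 2147483647  # 2^31 - 1
  h <- 104729
  for (x in v) {
    h <- (h * 69069 + (x %% m) + 1) %% m
    h <- (h * 69069 + 12345) %% m
  }
  as.integer(h)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
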