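`%||%` <- function(a, b) if (is.null(a)) b else a

# one positive finite scalar
check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single numeric value", name), call. = FALSE)
  if (!allow_inf && !is.finite(x))
    stop(sprintf("'%s' must be finite", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

#' Spawn reproducible sub-seeds from a master seed
#'
#' Used by the pipeline so that per-subject simulation streams can be rerun
#' in isolation with identical results. Seeds stay below 2^31 (R integers).
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of length \code{n}.
#' @export
spawn_seeds <- function(seed, n) {
  check_scalar(seed, "seed")
  check_scalar(n, "n", positive = TRUE)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, as.integer(n))
}
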