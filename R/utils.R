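# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG state
#'
#' All synthetic-data generators funnel their randomness through this helper so
#' that they are pure functions of `(config, seed)`: the caller's RNG state is
#' saved and restored, and the generator always sees the same stream.
#'
#' @param seed Single integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# log10 of sum(10^x) without underflow; x may contain -Inf
log10_sum_exp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log10(sum(10^(x - m)))
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

chng3_log <- function(fmt, ..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}
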