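# Internal helpers shared across modules.

#' Evaluate an expression with a fixed RNG seed, restoring the caller's stream
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  force(code)
}

# Derive an independent child seed from a master seed and a stream index.
# Kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647) + 1L
}

stop_field <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)

assert_prob <- function(x, name, open_right = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 &&
    (if (open_right) x < 1 else x <= 1)
  if (!ok) stop_field("'%s' must be in [0,%s), got %s", name,
                      if (open_right) "1" else "1]", format(x))
  invisible(x)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_field("'%s' must be a positive number, got %s", name, format(x))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
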