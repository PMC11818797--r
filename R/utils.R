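# Internal helpers shared across the package.

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` after seeding the generator with `seed`, then restores the
#' caller's RNG state so library functions never disturb user-level
#' reproducibility.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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

# Deterministic per-stream seed derivation. A small multiplicative hash keeps
# derived seeds inside the 32-bit integer range while decorrelating streams
# that share a master seed.
derive_seed <- function(seed, index) {
  m <- 2147483629  # largest prime < 2^31
  s <- (as.double(seed) %% m)
  s <- (s * 48271 + as.double(index) * 16807 + 11) %% m
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop_invalid("%s contains non-finite values (NaN/Inf/NA)", what)
  }
  invisible(TRUE)
}
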