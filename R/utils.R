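#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state so package functions never clobber user randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed from a master seed and a stream index,
# kept inside 32-bit integer range.
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %%
               .Machine$integer.max)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Shoelace area of a polygon given vertex coordinates (closed implicitly).
polygon_area <- function(x, y) {
  n <- length(x)
  i2 <- c(2:n, 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
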