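#' @useDynLib kwarp, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx cor mad median quantile rnorm runif sd splinefun
#' @importFrom utils read.csv write.csv head tail
NULL

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# stopifnot() with a formatted message
assert_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
  invisible(TRUE)
}

# Linear interpolation that errors instead of extrapolating silently
interp1 <- function(x, y, xout) {
  approx(x, y, xout = xout, rule = 2)$y
}
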