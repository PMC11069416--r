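#' @importFrom rlang %||% abort warn .data
#' @importFrom stats fft mvfft rnorm runif rpois sd quantile IQR median
NULL

# deterministic 32-bit sub-seed derivation (independent of R's RNG state)
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  h <- 0
  for (k in ks) h <- (h * 69069 + (as.numeric(k) %% 2147483647) + 1) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lo || x > hi)
    abort(sprintf("`%s` must be a finite number in [%g, %g]", name, lo, hi))
  invisible(x)
}

euclid <- function(a, b) sqrt(sum((a - b)^2))
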