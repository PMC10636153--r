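## Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `code` after seeding the RNG with `seed`, then restores the caller's
#' RNG state, so library functions do not clobber user-level reproducibility.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(code)
}

## derive a child seed from a base seed; keeps results < 2^31
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1009L + as.integer(offset)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)

## Gaussian kernel on a regular grid, mass-normalised, truncated at 5 SD
gauss_kernel <- function(bw, step) {
  half <- max(1L, ceiling(5 * bw / step))
  t <- seq(-half, half) * step
  k <- exp(-0.5 * (t / bw)^2)
  k / sum(k) / step
}

## linear convolution of y with kernel k (centered), same length as y,
## with edge renormalisation by the local kernel mass
conv_same <- function(y, k, step, edge_correct = TRUE) {
  n <- length(y)
  m <- length(k)
  full <- convolve(y, rev(k), type = "open") * step
  half <- (m - 1L) %/% 2L
  out <- full[(half + 1L):(half + n)]
  if (edge_correct) {
    mass <- convolve(rep(1, n), rev(k), type = "open") * step
    out <- out / mass[(half + 1L):(half + n)]
  }
  out
}
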