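## internal helpers

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package functions
#' do not disturb user-level reproducibility. A NULL seed evaluates the code
#' under the current RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' @noRd
next_pow2 <- function(n) {
  stopifnot(n >= 1)
  2L^ceiling(log2(n))
}

#' @noRd
stop_planeeg <- function(...) stop(..., call. = FALSE)

#' Linear convolution via FFT, returning the 'same'-aligned segment
#' compensated for the group delay of a symmetric odd-length kernel.
#' @noRd
fft_conv_same <- function(x, h) {
  n <- length(x)
  L <- length(h)
  nfft <- next_pow2(n + L - 1L)
  y <- Re(fft(fft(c(x, numeric(nfft - n))) * fft(c(h, numeric(nfft - L))),
              inverse = TRUE)) / nfft
  d <- (L - 1L) %/% 2L
  y[(d + 1L):(d + n)]
}

## derive a vector of sub-seeds (< 2^31) from one master seed
#' @noRd
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
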