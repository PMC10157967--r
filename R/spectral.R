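#' Discrete prolate spheroidal sequence (Slepian) tapers
#'
#' Computes the `k` most spectrally concentrated tapers of length `n` for
#' time-half-bandwidth product `nw`, as eigenvectors of the symmetric
#' tridiagonal Slepian matrix. The largest eigenvalues are located by
#' Sturm-sequence bisection and the eigenvectors recovered by inverse
#' iteration with a tridiagonal (Thomas) solve, so the cost is O(n) per
#' taper rather than O(n^3) for a dense eigendecomposition. Tapers are
#' unit-energy, mutually orthogonal, and follow the usual polarity
#' convention (odd-order tapers have positive mean, even-order tapers start
#' with a positive slope).
#'
#' @param n taper length, samples.
#' @param nw time-half-bandwidth product (e.g. 6 for 6 s epochs with
#'   +/- 1 Hz smoothing).
#' @param k number of tapers (conventionally `2 * nw - 1`).
#' @return n x k matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k) {
  stopifnot(n >= 2, nw > 0, k >= 1, k <= n)
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  if (!is.null(the[[key]])) return(the[[key]])
  t <- 0:(n - 1)
  d <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * nw / n)
  e <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  vals <- tridiag_eig_largest(d, e, k)
  V <- matrix(0, n, k)
  for (j in seq_len(k)) {
    v <- sin(seq_len(n) * (j + sqrt(2)))   # deterministic start vector
    v <- v / sqrt(sum(v^2))
    for (it in 1:5) {
      v <- tridiag_solve(d, e, vals[j], v)
      if (j > 1) {
        prev <- V[, seq_len(j - 1), drop = FALSE]
        v <- v - prev %*% crossprod(prev, v)
      }
      v <- v / sqrt(sum(v^2))
    }
    ok <- if (j %% 2 == 1) sum(v) >= 0 else sum(((n - 1):0) * v) >= 0
    if (!ok) v <- -v
    V[, j] <- v
  }
  the[[key]] <- V
  V
}

## number of eigenvalues of tridiag(d, e) strictly below x (Sturm count)
sturm_count <- function(d, e, x) {
  n <- length(d)
  cnt <- 0L
  q <- d[1] - x
  if (q < 0) cnt <- 1L
  for (i in 2:n) {
    q <- if (q == 0) d[i] - x - abs(e[i - 1]) / .Machine$double.eps
         else d[i] - x - e[i - 1]^2 / q
    if (q < 0) cnt <- cnt + 1L
  }
  cnt
}

## k largest eigenvalues of tridiag(d, e), by bisection within Gershgorin bounds
tridiag_eig_largest <- function(d, e, k) {
  n <- length(d)
  rad <- c(abs(e[1]), abs(e[-(n - 1)]) + abs(e[-1]), abs(e[n - 1]))
  lo0 <- min(d - rad); hi0 <- max(d + rad)
  vals <- numeric(k)
  for (j in seq_len(k)) {
    lo <- lo0; hi <- hi0
    for (it in 1:100) {
      mid <- (lo + hi) / 2
      if (sturm_count(d, e, mid) > n - j) hi <- mid else lo <- mid
      if (hi - lo <= .Machine$double.eps * max(abs(lo), abs(hi), 1)) break
    }
    vals[j] <- (lo + hi) / 2
  }
  vals
}

## Thomas solve of (tridiag(d, e) - lam I) v = b, with pivot guard for the
## near-singular systems inverse iteration requires
tridiag_solve <- function(d, e, lam, b) {
  n <- length(d)
  dd <- d - lam
  cp <- numeric(n - 1); dp <- numeric(n)
  den <- dd[1]; if (abs(den) < 1e-300) den <- 1e-300
  cp[1] <- e[1] / den; dp[1] <- b[1] / den
  for (i in 2:n) {
    den <- dd[i] - e[i - 1] * cp[i - 1]
    if (abs(den) < 1e-300) den <- 1e-300
    if (i < n) cp[i] <- e[i] / den
    dp[i] <- (b[i] - e[i - 1] * dp[i - 1]) / den
  }
  v <- numeric(n)
  v[n] <- dp[n]
  for (i in (n - 1):1) v[i] <- dp[i] - cp[i] * v[i + 1]
  v
}

#' Build the canonical log-spaced frequency grid
#'
#' `nsteps` logarithmically spaced target frequencies between `fmin` and
#' `fmax`, each snapped to the nearest DFT bin obtained after zero-padding
#' epochs to the next power of two (6 s at 500 Hz: 3000 samples padded to
#' 4096, bin width 500/4096 = 0.1220703125 Hz). The default 23-step
#' 0.5-20 Hz grid starts at 0.488 Hz (4 bins) and ends at 20.019 Hz
#' (164 bins); the 44-step 0.5-80 Hz variant serves wide-band analyses.
#' Targets snapping to the same bin are collapsed with a warning.
#'
#' @param fmin,fmax band limits, Hz (0 < fmin < fmax < fs/2).
#' @param nsteps number of log-spaced steps (>= 2).
#' @param epoch_length epoch duration, seconds.
#' @param fs sampling rate, Hz.
#' @return object of class `"frequency_grid"`: `centers` (Hz), `bins`
#'   (integer DFT bin indices, center = bin * bin_width), `bin_width`,
#'   `pad_length`, `fmin`, `fmax`, `nsteps`, `epoch_length`, `fs`.
#' @export
build_frequency_grid <- function(fmin = 0.5, fmax = 20, nsteps = 23,
                                 epoch_length = 6, fs = 500) {
  if (!(fmin > 0 && fmax > fmin)) stop_planeeg("need 0 < fmin < fmax")
  if (fmax >= fs / 2)
    stop_planeeg(sprintf("fmax = %g Hz must be below Nyquist (%g Hz)",
                         fmax, fs / 2))
  if (nsteps < 2) stop_planeeg("'nsteps' must be >= 2")
  n_samples <- round(epoch_length * fs)
  pad <- next_pow2(n_samples)
  bw <- fs / pad
  targets <- exp(seq(log(fmin), log(fmax), length.out = nsteps))
  bins <- round(targets / bw)
  if (anyDuplicated(bins)) {
    warning("log-spaced targets collapse onto shared DFT bins; duplicates dropped")
    bins <- unique(bins)
  }
  structure(list(centers = bins * bw, bins = as.integer(bins), bin_width = bw,
                 pad_length = pad, fmin = fmin, fmax = fmax,
                 nsteps = as.integer(nsteps), epoch_length = epoch_length,
                 fs = fs),
            class = "frequency_grid")
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("<frequency_grid> %d centers, %.3f-%.3f Hz (bin %.10g Hz, pad %d)\n",
              length(x$centers), min(x$centers), max(x$centers),
              x$bin_width, x$pad_length))
  invisible(x)
}

#' DPSS multitaper power spectral density
#'
#' One-sided PSD by the multitaper method: each epoch is multiplied by
#' `K = 2 * epoch_length * smoothing - 1` unit-energy DPSS tapers
#' (time-half-bandwidth `epoch_length * smoothing`; K = 11 for 6 s epochs
#' with +/- 1 Hz smoothing), zero-padded to the grid's FFT length, and the
#' squared DFT magnitudes are averaged over tapers, epochs and channels.
#' Density normalization is `2 / fs` at interior bins, so integrating the
#' full-band estimate recovers the signal variance.
#'
#' @param epochs an `"epoch_set"` (after artifact rejection, typically).
#' @param grid a [build_frequency_grid()]; NULL returns the full bin grid
#'   from 0 to Nyquist.
#' @param smoothing spectral half-bandwidth W in Hz (the +/- W multitaper
#'   smoothing); must give at least one taper.
#' @return object of class `"psd"`: `freq` (Hz), `power` (uV^2/Hz),
#'   `n_tapers`, `n_epochs`, `smoothing`, `fs`.
#' @export
multitaper_psd <- function(epochs, grid = NULL, smoothing = 1) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  n_epochs <- d[1]; n_channels <- d[2]; n <- d[3]
  T_len <- epochs$epoch_length
  K <- round(2 * T_len * smoothing - 1)
  if (K < 1)
    stop_planeeg(sprintf("smoothing %g Hz over %g s epochs gives < 1 taper",
                         smoothing, T_len))
  nw <- T_len * smoothing
  pad <- if (is.null(grid)) next_pow2(n) else grid$pad_length
  if (!is.null(grid) && pad < n)
    stop_planeeg("grid pad_length is shorter than the epoch")
  tapers <- dpss_tapers(n, nw, K)
  acc <- numeric(pad %/% 2 + 1)
  zeros <- matrix(0, pad - n, n_epochs)
  for (ch in seq_len(n_channels)) {
    X <- t(epochs$data[, ch, , drop = FALSE][, 1, ])   # n x n_epochs
    if (n_epochs == 1L) X <- matrix(epochs$data[1, ch, ], ncol = 1L)
    X <- sweep(X, 2, colMeans(X))        # demean each epoch before tapering
    for (k in seq_len(K)) {
      Y <- stats::mvfft(rbind(X * tapers[, k], zeros))
      acc <- acc + rowSums(abs(Y[seq_len(pad %/% 2 + 1), , drop = FALSE])^2)
    }
  }
  pw <- acc / (K * n_epochs * n_channels) / epochs$fs
  pw[2:(pad %/% 2)] <- 2 * pw[2:(pad %/% 2)]           # one-sided doubling
  freq_all <- (0:(pad %/% 2)) * epochs$fs / pad
  if (is.null(grid)) {
    freq <- freq_all; power <- pw
  } else {
    freq <- grid$centers; power <- pw[grid$bins + 1L]
  }
  structure(list(freq = freq, power = power, n_tapers = K,
                 n_epochs = n_epochs, smoothing = smoothing, fs = epochs$fs),
            class = "psd")
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("<psd> %d frequencies (%.3f-%.3f Hz), %d tapers, %d epoch(s)\n",
              length(x$freq), min(x$freq), max(x$freq), x$n_tapers,
              x$n_epochs))
  invisible(x)
}

#' Fit the aperiodic 1/f^x component of a spectrum
#'
#' Ordinary least squares of log10(power) on log10(frequency) over the grid
#' centers inside `fit_range`; the aperiodic exponent x is the negated
#' slope, so x = 0 is a flat (white-noise) spectrum and larger x means a
#' steeper decay. Non-positive powers are excluded with a warning; fewer
#' than 3 surviving points is an error. The fit is exact on noiseless
#' power-law input.
#'
#' @param psd a `"psd"` object, or a numeric power vector (then `freq` must
#'   be given).
#' @param fit_range `c(lo, hi)` in Hz (inclusive); NULL (the default) fits
#'   over every positive-frequency point supplied, i.e. the whole grid
#'   including its snapped endpoint bins (0.488 and 20.019 Hz for the
#'   default grid).
#' @param freq frequencies matching a bare power vector.
#' @return object of class `"aperiodic_fit"`: `exponent`, `offset`
#'   (log10 uV^2/Hz intercept at 1 Hz), `r_squared`, `fit_range`,
#'   `n_points`.
#' @export
fit_aperiodic <- function(psd, fit_range = NULL, freq = NULL) {
  if (inherits(psd, "psd")) {
    freq <- psd$freq; power <- psd$power
  } else {
    power <- as.numeric(psd)
    if (is.null(freq) || length(freq) != length(power))
      stop_planeeg("bare power vectors need a matching 'freq'")
  }
  sel <- freq > 0
  if (!is.null(fit_range))
    sel <- sel & freq >= fit_range[1] & freq <= fit_range[2]
  if (any(power[sel] <= 0)) {
    warning("non-positive power at some in-range frequencies; excluded from fit")
    sel <- sel & power > 0
  }
  if (sum(sel) < 3)
    stop_planeeg("fewer than 3 positive-power frequencies in the fit range")
  lx <- log10(freq[sel]); ly <- log10(power[sel])
  fit <- stats::lm(ly ~ lx)
  ## guard: an exactly flat spectrum has zero total variation, R^2 -> 1
  ss_tot <- sum((ly - mean(ly))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  r2 <- if (ss_tot <= .Machine$double.eps * length(ly)) 1
        else 1 - ss_res / ss_tot
  structure(list(exponent = -unname(stats::coef(fit)[2]),
                 offset = unname(stats::coef(fit)[1]),
                 r_squared = max(0, min(1, r2)),
                 fit_range = range(freq[sel]), n_points = sum(sel)),
            class = "aperiodic_fit")
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf("<aperiodic_fit> x = %.3f (offset %.3f, R^2 = %.3f, %d points, %g-%g Hz)\n",
              x$exponent, x$offset, x$r_squared, x$n_points,
              x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Collect per-dataset spectra into a spectrum set
#'
#' @param power dataset x frequency matrix (rows in `labels` order).
#' @param grid the shared [build_frequency_grid()].
#' @param labels group label per dataset.
#' @param ids optional dataset identifiers.
#' @return object of class `"spectrum_set"`.
#' @export
spectrum_set <- function(power, grid, labels, ids = NULL) {
  power <- as.matrix(power)
  stopifnot(inherits(grid, "frequency_grid"),
            ncol(power) == length(grid$centers),
            nrow(power) == length(labels))
  if (any(power < 0)) stop_planeeg("power must be non-negative")
  if (is.null(ids)) ids <- paste0("dataset", seq_len(nrow(power)))
  rownames(power) <- ids
  colnames(power) <- sprintf("%.3f", grid$centers)
  structure(list(power = power, grid = grid, labels = as.character(labels),
                 ids = ids),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d dataset(s) x %d frequencies\n",
              nrow(x$power), ncol(x$power)))
  print(table(x$labels))
  invisible(x)
}

#' Plot spectra on log-log axes
#'
#' Individual datasets as thin lines, group means as heavy lines.
#'
#' @param x a `"spectrum_set"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.spectrum_set <- function(x, ...) {
  groups <- unique(x$labels)
  cols <- grDevices::hcl.colors(max(3, length(groups)), "Dark 3")
  graphics::matplot(x$grid$centers, t(x$power), type = "l", lty = 1,
                    col = grDevices::adjustcolor(cols[match(x$labels, groups)],
                                                 alpha.f = 0.3),
                    log = "xy", xlab = "Frequency (Hz)",
                    ylab = expression(paste("PSD (", mu, V^2, "/Hz)")), ...)
  for (i in seq_along(groups)) {
    m <- colMeans(x$power[x$labels == groups[i], , drop = FALSE])
    graphics::lines(x$grid$centers, m, col = cols[i], lwd = 3)
  }
  graphics::legend("bottomleft", legend = groups, col = cols[seq_along(groups)],
                   lwd = 3, bty = "n")
  invisible(x)
}
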