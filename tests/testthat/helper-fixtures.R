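# shared fixtures and independent oracles, built in code at test time

# wrap an epoch x channel x sample array as an epoch_set without running the
# preprocessing chain
make_epoch_set <- function(a, fs = 500, epoch_length = dim(a)[3] / fs) {
  structure(list(data = a, fs = fs, epoch_length = epoch_length,
                 channel_labels = paste0("ch", seq_len(dim(a)[2])),
                 group = NA_character_, source = "fixture"),
            class = "epoch_set")
}

# seeded Gaussian epochs: n_epochs x n_channels x n_samples
gaussian_epochs <- function(n_epochs, n_samples, n_channels = 1, seed = 1,
                            fs = 500) {
  set.seed(seed)
  make_epoch_set(array(rnorm(n_epochs * n_channels * n_samples),
                       dim = c(n_epochs, n_channels, n_samples)), fs = fs)
}

# independent log-log least-squares slope of the raw periodogram, used as the
# oracle for the colored-noise generator (no multitaper machinery involved)
periodogram_slope <- function(x, fs, fmin = 1, fmax = 100) {
  n <- length(x)
  P <- abs(fft(x))^2 / n
  f <- (1:(n %/% 2)) * fs / n
  sel <- f >= fmin & f <= fmax
  unname(coef(lm(log(P[2:(n %/% 2 + 1)][sel]) ~ log(f[sel])))[2])
}

# brute-force reimplementation of the rejection rule, straight from the
# written description and independent of the package internals
bruteforce_reject <- function(epochs, peak_k = 5, dist_k = 2.5) {
  d <- dim(epochs$data)
  cells <- expand.grid(e = seq_len(d[1]), ch = seq_len(d[2]))
  met <- t(apply(cells, 1, function(r) {
    x <- epochs$data[r[1], r[2], ]
    pooled <- as.vector(epochs$data[, r[2], ])
    m2 <- mean((x - mean(x))^2)
    c(peak = max(abs(x)),
      variance = var(x),
      zvalue = mean(abs(x - mean(pooled)) / sd(pooled)),
      kurtosis = if (m2 > 0) mean((x - mean(x))^4) / m2^2 else 0)
  }))
  bad <- abs(met[, "peak"] - mean(met[, "peak"])) > peak_k * sd(met[, "peak"])
  for (m in c("variance", "zvalue", "kurtosis"))
    bad <- bad | met[, m] > mean(met[, m]) + dist_k * sd(met[, m])
  sort(unique(cells$e[bad]))
}

# semi-analytic expected pipeline exponent for a true power-law input:
# convolve the two-pass-filtered f^-x spectrum with the mean DPSS spectral
# window, then apply the same log-log OLS over the grid. Independent of the
# time-domain simulation path.
predicted_pipeline_exponent <- function(x_true, nf = 2^15) {
  fs <- 500; n <- 3000
  tap <- dpss_tapers(n, 6, 11)
  hp <- design_fir(fs, "highpass", 0.1)
  lp <- design_fir(fs, "lowpass", 23)
  g <- build_frequency_grid()
  f <- (1:(nf / 2)) * fs / nf
  S <- f^(-x_true) * fir_response(hp, f, two_pass = TRUE)^2 *
    fir_response(lp, f, two_pass = TRUE)^2
  W <- matrix(0, nf, 11)
  for (k in 1:11) W[, k] <- abs(fft(c(tap[, k], numeric(nf - n))))^2
  Wf <- rowMeans(W)
  est <- vapply(g$centers, function(f0) {
    shift <- round(f0 / (fs / nf))
    idx <- abs((1:(nf / 2)) - shift)
    w <- Wf[pmin(idx, nf - idx) + 1]
    sum(w * S) / sum(Wf) * 2
  }, numeric(1))
  fit_aperiodic(est, freq = g$centers)$exponent
}

# full characterization of one synthetic recording, as the pipeline does it
pipeline_exponent <- function(x_true, seed, duration = 600, fs = 500) {
  rec <- recording(generate_colored_noise(duration * fs, fs, x_true,
                                          seed = seed), fs)
  ep <- preprocess_recording(rec, preprocess_config())
  rep <- autoreject(ep)
  fit_aperiodic(multitaper_psd(drop_rejected(ep, rep),
                               build_frequency_grid()))$exponent
}

# Dark-vs-light permutation p-values and significance pattern as printed in
# the published comparison table (23 log-spaced frequencies, 0.488-20.019 Hz)
published_p_dark_light <- c(0.0001, 0.0001, 0.0001, 0.0001, 0.0001, 0.0001,
                            0.0050, 0.0831, 0.0168, 0.0035, 0.0027, 0.0007,
                            0.0001, 0.0001, 0.0001, 0.0001, 0.0001, 0.0001,
                            0.0001, 0.0001, 0.0001, 0.0001, 0.0001)
published_sig_dark_light <- c(rep(TRUE, 6), rep(FALSE, 5), rep(TRUE, 12))

# the 23 grid frequencies as printed (truncated to 3 decimals)
published_grid <- c(0.488, 0.610, 0.732, 0.854, 0.976, 1.098, 1.342, 1.586,
                    1.953, 2.319, 2.685, 3.173, 3.784, 4.394, 5.249, 6.225,
                    7.324, 8.666, 10.253, 12.084, 14.282, 16.967, 20.019)
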