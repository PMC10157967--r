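#' Generate power-law (1/f^x) background noise
#'
#' Draws Gaussian white noise and shapes its spectrum in one pass: the DFT
#' amplitude at frequency f is scaled by f^(-x/2) (the DC bin is zeroed, so
#' the power at f = 0 is finite), the result is inverted and standardized to
#' zero mean and unit sample variance. The expected periodogram then follows
#' f^(-x) over (0, fs/2); x = 0 recovers white noise.
#'
#' @param n_samples number of samples (>= 2).
#' @param fs sampling rate, Hz.
#' @param exponent target aperiodic exponent x (>= 0, finite). Planarian-like
#'   recordings show x around 1.2-1.5; recordings of dead tissue in the same
#'   setup show much steeper slopes near 2.7.
#' @param seed optional integer; identical seed and arguments give
#'   bit-identical output, and the caller's RNG state is left untouched.
#' @return numeric vector of length `n_samples`, zero mean, unit variance.
#' @export
generate_colored_noise <- function(n_samples, fs, exponent, seed = NULL) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 2)
    stop_planeeg("'n_samples' must be a single integer >= 2")
  if (!is.numeric(exponent) || length(exponent) != 1L ||
      !is.finite(exponent) || exponent < 0)
    stop_planeeg("'exponent' must be a single finite value >= 0")
  n <- as.integer(n_samples)
  with_seed(seed, {
    w <- stats::rnorm(n)
    X <- stats::fft(w)
    k <- seq_len(n) - 1L
    f <- pmin(k, n - k) * fs / n          # two-sided frequency magnitude
    amp <- c(0, f[-1]^(-exponent / 2))    # DC zeroed
    x <- Re(stats::fft(X * amp, inverse = TRUE)) / n
    as.numeric(scale(x))                  # zero mean, unit sample variance
  })
}

#' Generate a band-limited oscillatory component
#'
#' Narrow-band Gaussian noise synthesized in the frequency domain: complex
#' Gaussian spectrum weighted by a Gaussian envelope centered on `freq` with
#' standard deviation `bandwidth / 2`, inverted and standardized, then scaled
#' by `amplitude` (in units of the background SD, which the generator fixes
#' at 1).
#'
#' @param n_samples,fs as in [generate_colored_noise()].
#' @param freq center frequency, Hz (< fs/2).
#' @param bandwidth spectral full width, Hz.
#' @param amplitude SD of the component relative to the unit-SD background.
#' @param seed optional integer.
#' @return numeric vector of length `n_samples`.
#' @export
generate_oscillation <- function(n_samples, fs, freq, bandwidth = 1,
                                 amplitude = 1, seed = NULL) {
  if (freq >= fs / 2) stop_planeeg("oscillation frequency must be < fs/2")
  n <- as.integer(n_samples)
  with_seed(seed, {
    X <- stats::fft(stats::rnorm(n))
    k <- seq_len(n) - 1L
    f <- pmin(k, n - k) * fs / n
    env <- exp(-((f - freq)^2) / (2 * (bandwidth / 2)^2))
    env[1] <- 0
    x <- Re(stats::fft(X * env, inverse = TRUE)) / n
    amplitude * as.numeric(scale(x))
  })
}

#' Inject spike artifacts and power-line contamination
#'
#' Emulates the two dominant artifact classes seen in surface recordings of
#' immobilized planarians: large brief myogenic spikes, and sinusoidal
#' contamination at the power-line frequency and its (sub)harmonics
#' (25 / 50 / 100 Hz on a 50 Hz mains).
#'
#' Spikes are raised-cosine transients of 40 ms half-width (80 ms total,
#' shorter than one epoch), with random sign and uniform random placement;
#' the number of events is `round(spike_rate * duration_in_minutes)`, so the
#' injected count is exact. Each spike's peak magnitude equals
#' `spike_amplitude` times the input's standard deviation. Line components
#' are sinusoids with random phase and amplitude `amp` times the input SD
#' (for a zero-variance input the unit falls back to 1 uV).
#'
#' With `spike_rate = 0` and no line noise the input is returned unchanged.
#'
#' @param signal numeric vector, uV.
#' @param fs sampling rate, Hz.
#' @param spike_rate events per minute (>= 0).
#' @param spike_amplitude spike peak in multiples of the input SD.
#' @param line_noise list of `c(frequency_hz, amplitude)` pairs; all
#'   frequencies must be below fs/2.
#' @param seed optional integer.
#' @return numeric vector, same length as `signal`.
#' @export
inject_artifacts <- function(signal, fs, spike_rate = 0, spike_amplitude = 20,
                             line_noise = list(), seed = NULL) {
  if (spike_rate < 0) stop_planeeg("'spike_rate' must be >= 0")
  for (ln in line_noise) {
    if (ln[1] >= fs / 2)
      stop_planeeg(sprintf("line frequency %g Hz is at or above Nyquist (%g Hz)",
                           ln[1], fs / 2))
  }
  n <- length(signal)
  n_spikes <- round(spike_rate * n / fs / 60)
  if (n_spikes == 0 && length(line_noise) == 0) return(signal)
  s <- stats::sd(signal)
  unit <- if (s > 0) s else 1
  with_seed(seed, {
    out <- signal
    if (n_spikes > 0) {
      half <- round(0.040 * fs)                       # 40 ms half-width
      kernel <- 0.5 * (1 + cos(pi * (-half:half) / half))
      centers <- sample.int(n - 2L * half, n_spikes) + half
      signs <- sample(c(-1, 1), n_spikes, replace = TRUE)
      for (j in seq_len(n_spikes)) {
        idx <- (centers[j] - half):(centers[j] + half)
        out[idx] <- out[idx] + signs[j] * spike_amplitude * unit * kernel
      }
    }
    t <- (seq_len(n) - 1L) / fs
    for (ln in line_noise) {
      out <- out + ln[2] * unit * sin(2 * pi * ln[1] * t +
                                        stats::runif(1, 0, 2 * pi))
    }
    out
  })
}

#' Synthesis configuration for a simulated group study
#'
#' Defaults mirror the recording conditions the pipeline targets: 10-minute
#' single-channel recordings at 500 Hz, a power-law background whose exponent
#' depends on the experimental group (live planarians near 1.2-1.3 in
#' darkness/light; dead-tissue controls near 2.7), occasional large myogenic
#' spikes, and 50 Hz mains contamination with its sub- and first harmonic.
#'
#' @param n_datasets_per_group recordings per group (>= 2).
#' @param duration recording length, seconds.
#' @param fs sampling rate, Hz.
#' @param n_channels channels per recording.
#' @param exponent_per_group named numeric vector mapping group label to the
#'   target aperiodic exponent (all finite, >= 0).
#' @param oscillations list of `c(center_hz, bandwidth_hz, amplitude)`
#'   triples added to every recording (empty by default: planarian spectra
#'   show no discrete peaks).
#' @param spike_rate myogenic spike events per minute.
#' @param spike_amplitude spike peak in background-SD multiples.
#' @param line_noise list of `c(frequency_hz, amplitude)` pairs.
#' @param seed master seed; per-dataset seeds are derived from it.
#' @return object of class `"synthesis_config"`.
#' @export
synthesis_config <- function(n_datasets_per_group = 10,
                             duration = 600,
                             fs = 500,
                             n_channels = 1,
                             exponent_per_group = c(darkness = 1.23,
                                                    light = 1.31,
                                                    control = 2.72),
                             oscillations = list(),
                             spike_rate = 1,
                             spike_amplitude = 50,
                             line_noise = list(c(25, 0.2), c(50, 0.5),
                                               c(100, 0.2)),
                             seed = 1L) {
  stopifnot(n_datasets_per_group >= 1, duration > 0, fs > 0, n_channels >= 1)
  if (is.null(names(exponent_per_group)) || any(names(exponent_per_group) == ""))
    stop_planeeg("'exponent_per_group' must be a named vector of group exponents")
  if (any(!is.finite(exponent_per_group)) || any(exponent_per_group < 0))
    stop_planeeg("group exponents must be finite and >= 0")
  fmax <- max(c(0, vapply(line_noise, `[`, numeric(1), 1),
                vapply(oscillations, `[`, numeric(1), 1)))
  if (fs <= 2 * fmax)
    stop_planeeg("fs must exceed twice the highest injected frequency (Nyquist)")
  structure(
    list(n_datasets_per_group = as.integer(n_datasets_per_group),
         duration = duration, fs = fs, n_channels = as.integer(n_channels),
         exponent_per_group = exponent_per_group,
         oscillations = oscillations, spike_rate = spike_rate,
         spike_amplitude = spike_amplitude, line_noise = line_noise,
         seed = as.integer(seed)),
    class = "synthesis_config")
}

#' Simulate a between-subjects group study
#'
#' Builds `n_datasets_per_group` recordings per group: a power-law background
#' at that group's exponent, plus any configured oscillations, spikes, and
#' line noise. Every recording gets its own sub-seed derived from the master
#' seed, so the whole study is bit-reproducible, and each recording's
#' metadata records its group, seed, and generation parameters.
#'
#' @param config a [synthesis_config()].
#' @return object of class `"group_study"`: list with `recordings` (named
#'   list of [recording()]s) and `manifest` (data.frame with id, group,
#'   exponent, seed).
#' @export
simulate_group_study <- function(config) {
  stopifnot(inherits(config, "synthesis_config"))
  groups <- names(config$exponent_per_group)
  if (length(groups) < 2 || config$n_datasets_per_group < 2)
    stop_planeeg("need at least two groups with at least two datasets each")
  n <- round(config$duration * config$fs)
  ids <- as.vector(t(outer(groups, seq_len(config$n_datasets_per_group),
                           function(g, i) sprintf("%s_%02d", g, i))))
  if (anyDuplicated(ids)) stop_planeeg("duplicate dataset identifiers")
  seeds <- derive_seeds(config$seed, length(ids))
  recs <- vector("list", length(ids))
  names(recs) <- ids
  manifest <- data.frame(id = ids,
                         group = rep(groups,
                                     each = config$n_datasets_per_group),
                         exponent = rep(unname(config$exponent_per_group),
                                        each = config$n_datasets_per_group),
                         seed = seeds)
  for (j in seq_along(ids)) {
    g_exp <- manifest$exponent[j]
    rec_data <- with_seed(seeds[j], {
      m <- matrix(0, config$n_channels, n)
      for (ch in seq_len(config$n_channels)) {
        x <- generate_colored_noise(n, config$fs, g_exp)
        for (osc in config$oscillations)
          x <- x + generate_oscillation(n, config$fs, osc[1], osc[2], osc[3])
        m[ch, ] <- inject_artifacts(x, config$fs, config$spike_rate,
                                    config$spike_amplitude, config$line_noise)
      }
      m
    })
    recs[[j]] <- recording(rec_data, config$fs, group = manifest$group[j],
                           source = "synthetic")
  }
  structure(list(recordings = recs, manifest = manifest, config = config),
            class = "group_study")
}

#' @export
print.group_study <- function(x, ...) {
  cat(sprintf("<group_study> %d recordings in %d group(s), %g s @ %g Hz\n",
              length(x$recordings), length(unique(x$manifest$group)),
              x$config$duration, x$config$fs))
  print(table(x$manifest$group))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' One file per recording (EDF or tab-delimited text with a time column),
#' plus a manifest (JSON or YAML) mapping filename to group label and seed.
#'
#' @param study a [simulate_group_study()] result.
#' @param dir output directory (created if missing).
#' @param format `"text"` or `"edf"`.
#' @param manifest_format `"json"` or `"yaml"`.
#' @return the manifest file path, invisibly.
#' @export
write_group_study <- function(study, dir, format = c("text", "edf"),
                              manifest_format = c("json", "yaml")) {
  stopifnot(inherits(study, "group_study"))
  format <- match.arg(format)
  manifest_format <- match.arg(manifest_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "edf") ".edf" else ".tsv"
  files <- file.path(dir, paste0(study$manifest$id, ext))
  for (j in seq_along(files))
    write_recording(study$recordings[[j]], files[j], format)
  man <- cbind(study$manifest, file = basename(files))
  man$fs <- study$config$fs
  mpath <- file.path(dir, paste0("manifest.",
                                 if (manifest_format == "json") "json" else "yaml"))
  if (manifest_format == "json") {
    jsonlite::write_json(man, mpath, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    yaml::write_yaml(lapply(seq_len(nrow(man)), function(i) as.list(man[i, ])),
                     mpath)
  }
  invisible(mpath)
}
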