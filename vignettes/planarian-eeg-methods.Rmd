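---
title: "Methods: spectral characterization of planarian surface EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral characterization of planarian surface EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planeeg)
```

## The measurement problem

Surface-electrode recordings from immobilized planarians are weak microvolt
signals riding on several aggressive contaminants: slow electrode and
amplifier drift, large brief myogenic spikes when the animal twitches, and
power-line interference at 50 Hz together with its first harmonic (100 Hz)
and subharmonic (25 Hz). The scientific questions — does the electrode pick
up neural activity at all, and does that activity respond to light — are
answered through two spectral summaries of each 10-minute recording:

* the **aperiodic exponent** x of the `1/f^x` background. In log-log
  coordinates the power spectral density of neural population activity is
  approximately linear with slope −x; x ≈ 0 is white noise, human EEG sits
  near 0.8–1.8, and recordings of dead tissue through the same hardware
  show much steeper slopes (strong low-frequency noise without the
  broadband mid-frequency activity of a living network);
* **band-wise oscillatory power** on a logarithmically spaced grid between
  0.5 and 20 Hz, compared between groups.

## Pipeline stages and their parameters

### FIR band-limiting

All filters are linear-phase Hamming-window FIRs applied forward and
backward (two passes), so phase is exactly zero and stopband attenuation
doubles in dB. The filter order follows the classic Hamming transition
rule `order = ceil(3.3 fs / Δf)`, rounded up to the next even integer so
the filter is type I. At fs = 500 Hz this gives:

| filter | −6 dB cutoff | transition Δf | order |
|---|---|---|---|
| high-pass | 0.1 Hz | 0.2 Hz | 8250 |
| low-pass | 23 Hz | 0.25 × cutoff = 5.75 Hz | 288 |
| notch (optional) | center ± 2 Hz | 1 Hz | 1650 |

The low-pass transition rule (a quarter of the cutoff) is the convention
that places the passband edge at 20.125 Hz, just above the top of the
analysis grid. The coefficients come from a windowed-sinc construction
(ideal response times Hamming window, unity gain renormalized in the
passband): a frequency-sampling design on a coarse grid cannot realize a
0.1 Hz cutoff at 500 Hz sampling, which is why the design is done directly.
The notches (25/50/100 Hz) only matter for the wide-band variant of the
analysis (0.5–80 Hz, 44-step grid); in the default 0.5–20 Hz band the
23 Hz low-pass already removes all line components.

Edge handling: before each pass the signal is extended by one kernel length
of odd-reflected samples. Startup transients still span roughly half the
filter order — about 8 s for the 8250-tap high-pass — so the 0.5 s edge
trim removes discontinuity artifacts, not the whole transient. This mirrors
the procedure being modeled; on stationary signals the residual transient
is negligible, but very short recordings should not be filtered with the
0.1 Hz high-pass.

### Epoching and automatic artifact rejection

After trimming 0.5 s per end, recordings are tiled into non-overlapping 6 s
epochs anchored at the trimmed start (a 600 s recording yields
floor(599/6) = 99 epochs); indices are 1-based throughout, as is idiomatic
in R. For every (channel, epoch) cell four metrics are computed: peak
|amplitude|, within-epoch variance, the mean absolute z-value of samples
standardized against the channel's pooled mean and SD, and within-epoch
kurtosis. Kurtosis uses the Pearson convention (Gaussian ≈ 3) by default —
the convention is exposed as a switch because removal decisions are
unaffected (the two conventions differ by a constant, and thresholds are
relative). Zero-variance cells report z and kurtosis as 0 with a warning
rather than an error, so flat-lined channels flow through to the retention
verdict.

Removal is single-pass: thresholds are computed once from all cells — peak
beyond 5 SD of the mean peak in either direction, or variance / z /
kurtosis more than 2.5 SD above their means (upper tail only, matching the
asymmetric wording of the procedure being modeled). Comparisons are strict,
which makes the degenerate zero-spread table well defined (nothing is
removed). Channels are judged by the same thresholds applied to their
metrics averaged over epochs; channel and epoch removal do not iterate. A
dataset is retained only if at least one channel and more than five epochs
survive.

A known property of single-pass relative thresholds: they assume artifacts
are rare. When more than roughly 15–20% of epochs contain spikes, the
contaminated cells inflate the metric table's own mean and SD enough that
the 5 SD peak criterion can fail to fire. The synthetic defaults (below)
deliberately stay in the sparse-artifact regime the procedure is designed
for.

### Multitaper spectral estimation

Each epoch is demeaned, multiplied by K discrete prolate spheroidal
sequence (DPSS) tapers, zero-padded from 3000 to 4096 samples, and the
squared DFT magnitudes are averaged over tapers, epochs, and surviving
channels, normalized to one-sided density (µV²/Hz). With epoch duration
T = 6 s and half-bandwidth W = 1 Hz ("±1 Hz smoothing"), the standard
taper count is K = 2TW − 1 = 11. The tapers are computed from the
symmetric tridiagonal Slepian matrix: the 11 largest eigenvalues by
Sturm-sequence bisection, eigenvectors by inverse iteration with a Thomas
solve — O(n) per taper, cached per (n, NW, K), and matching the standard
reference implementation to ~1e-13.

The analysis grid is 23 logarithmically spaced targets between 0.5 and
20 Hz, each snapped to the nearest DFT bin of width 500/4096 =
0.1220703125 Hz; the padded FFT length (4096, next power of two above the
epoch's 3000 samples) is exactly the choice that makes the grid run from
0.488 to 20.019 Hz. Snapping can collapse neighboring targets onto one bin
when the requested grid is finer than the bin width (this happens at the
low end of the 44-step 0.5–80 Hz variant); duplicates are dropped with a
warning.

### Aperiodic fit

The exponent is the negated slope of an ordinary least-squares fit of
log10 power on log10 frequency over the grid (all 23 points by default;
non-positive powers are excluded with a warning, and fewer than three
usable points is an error). The fit is exact on noiseless power laws. No
peak model is removed first: planarian spectra show no discrete peaks, and
a peak-aware decomposition is out of scope.

**Estimator bias on steep spectra.** A ±1 Hz smoothing bandwidth is wider
than the lowest octave of the grid, so the estimate at 0.488–1.1 Hz is a
weighted average of the true spectrum over roughly [0, 1.5] Hz. For steep
spectra the strong 0.2–0.5 Hz power (passed by the 0.1 Hz high-pass)
inflates those six grid points, which *steepens* the fitted slope. The
package quantifies this with a semi-analytic prediction — the filtered
`f^-x` spectrum convolved with the mean DPSS spectral window, then the same
OLS fit — which the test suite checks against simulation. Through the full
chain, true exponents 0.5 / 1.0 / 1.5 / 2.7 are estimated at roughly
0.49 / 1.05 / 1.63 / 3.11 (±1 Hz smoothing, 99 epochs). Shallow slopes
(x ≤ 1, including the white-noise null) are recovered essentially
unbiased; steep slopes are inflated by an amount the estimator itself
predicts. This is a property of the published measurement chain, not of the
implementation — it is one plausible source of the low-frequency "plateau"
such recordings show — and it means fitted exponents for steep-spectrum
(dead-control-like) data should be read as pipeline-scale values, not as
the underlying physical slope. A knee-aware spectral parameterization
would mitigate it, but is deliberately out of scope.

### Group statistics

Per frequency, the observed statistic is a pooled-variance two-sample t on
log10 power (spectra span orders of magnitude; a linear-power switch is
provided). Group labels are randomly reassigned 10,000 times, the same
reassignment at every frequency so cross-frequency dependence is
preserved; the two-tailed p is the fraction of permutations with
|t| ≥ |t_obs|, floored at 1/n_permutations (0.0001 at the default count).
Whether the observed assignment is included in the null set is a
convention; both choices round to the floor at 10,000 permutations, and the
package counts permuted draws only.

Across the 23 frequencies, significance is controlled by the
**Benjamini–Yekutieli** step-up FDR procedure at q = 0.01 (sorted p(i)
against (i/m)·q / Σ 1/j). BY rather than plain Benjamini–Hochberg is a
substantive identification: applied to the published dark-vs-light
p-values, only the dependency-robust BY variant reproduces the published
significance pattern (BH additionally flags the 2.3–2.7 Hz band). The
critical alpha of 0.01 for the exponent contrasts reflects a Bonferroni
split of 0.05 over three pairwise group comparisons. Exponent contrasts use
Welch's unequal-variance t with Welch–Satterthwaite degrees of freedom and
a 95% CI, delegated to `stats::t.test()`.

## The synthetic-recording generator

`simulate_group_study()` emulates the statistical structure the analysis
assumes, with every draw governed by one master seed (per-dataset sub-seeds
are derived from it, so studies are bit-reproducible and individual
recordings independent):

* **Background**: Gaussian noise spectrally shaped in one DFT pass —
  amplitude at frequency f scaled by `f^(-x/2)`, DC zeroed, inverted,
  standardized to zero mean and unit variance. The expected periodogram is
  exactly `f^-x` across (0, fs/2); an AR approximation would only be
  asymptotically correct and much harder to verify.
* **Defaults**: 10-minute, single-channel, 500 Hz recordings; group
  exponents darkness 1.23, light 1.31, control 2.72 (the reported group
  means of the study this pipeline models). Channel count and amplitude
  scale are conventions (amplitudes are in background-SD units), since
  neither is constrained by published values.
* **Oscillations** (off by default — planarian spectra show no discrete
  peaks): narrow-band Gaussian components synthesized in the frequency
  domain with a Gaussian envelope of chosen center, bandwidth, and relative
  amplitude.
* **Myogenic spikes**: raised-cosine transients of 40 ms half-width (80 ms
  total — long enough to move epoch variance and kurtosis, much shorter
  than an epoch), random sign, peak equal to `spike_amplitude` × input SD.
  The count is deterministic, `round(rate × minutes)` with uniform seeded
  placement, so injected events are exactly countable in tests. Defaults
  are 1/min at 50 SD: large and sparse, the regime in which the single-pass
  rejection thresholds reliably remove every spike epoch (at several times
  that rate the contaminated cells inflate the thresholds and the
  procedure degrades — a documented limitation, not a target regime).
* **Line noise**: sinusoids at 25/50/100 Hz with seeded phase, amplitudes
  relative to the input SD (for a zero-variance input the unit falls back
  to 1 µV so tones can be injected into silence).

What the generator does *not* emulate: nonstationarity (drifting artifact
rates, state changes within a recording), electrode contact changes,
non-sinusoidal line interference, or any biophysics of the planarian
ganglia. Passing tests therefore demonstrate that the pipeline measures
what it claims on signals with the assumed stationary statistical
structure — not that real recordings satisfy those assumptions.

## Numerical and design choices

* **Seeding**: every stochastic function takes an explicit seed and
  restores the caller's RNG state; derived sub-seeds stay below 2³¹.
* **Determinism**: identical configuration and seeds give bit-identical
  recordings, spectra, p-values, and a byte-identical `summary.json` (the
  summary deliberately carries no timestamps).
* **Degenerate inputs**: zero-variance cells warn and report 0 (rejection
  still works through the peak metric); non-positive powers are excluded
  from the log-log fit with a warning; an exactly flat spectrum reports
  R² = 1 (zero total variation is a perfect power-law fit with x = 0);
  signals not longer than the filter order, sub-epoch recordings,
  mismatched grids, and empty p-vectors are errors with specific messages.
* **Strictness at thresholds**: rejection uses strict inequalities so the
  zero-spread metric table removes nothing; FDR flags use ≤ at the step-up
  boundary.
* **Problem sizes in the test suite**: unit tests run scaled-down studies
  (2-minute recordings, hundreds of permutations) chosen so every stage is
  exercised with comfortable statistical margins; the acceptance suite
  runs the study-scale conditions (10-minute recordings, 20 replicates per
  exponent level, 500-replicate null calibration at 1,000 permutations,
  10,000-permutation floor check with groups of 14 and 11). The null
  calibration generates 66 s datasets (10 epochs each), since the
  permutation test's calibration is invariant to dataset length.
* **EDF**: the reader/writer implements standard 16-bit EDF (ASCII
  headers, little-endian int16 records, per-channel physical scaling);
  round trips are exact up to the 16-bit quantization step. Mixed
  per-channel sampling rates are rejected — the pipeline operates on
  rectangular channel × sample arrays.

## Known limitations

* Steep aperiodic slopes (x ≳ 1.5) are systematically inflated by the
  prescribed smoothing bandwidth, as quantified above.
* The artifact-rejection thresholds degrade when artifacts stop being
  rare (≳ 15–20% of epochs).
* The 0.1 Hz high-pass transient exceeds the 0.5 s trim; recordings
  shorter than a few minutes inherit edge contamination.
* Permutation p-values at the floor are reported as 1/n_permutations, not
  as zero; with very small groups the identical label assignment can be
  redrawn, which bounds attainable significance.
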