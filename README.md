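# planeeg

Spectral characterization of surface-electrode EEG recordings from
planarian flatworms (and similarly small, slow nervous systems).

Planarians (*Schmidtea mediterranea*) carry paired cephalic ganglia of about
50,000 neurons and are strongly photophobic, which makes darkness-vs-light
contrasts a natural probe of whether a noninvasive surface electrode picks up
neural activity at all. The resulting recordings are difficult: microvolt
signals at 500 Hz, contaminated by large myogenic spikes, power-line
interference at 50 Hz with sub- and higher harmonics (25, 100 Hz), and
strong low-frequency drift. `planeeg` implements the complete
characterization pipeline for such data:

1. **Preprocessing** — zero-phase two-pass Hamming-window FIR filters
   (high-pass 0.1 Hz, low-pass 23 Hz, optional notches at 25/50/100 Hz; the
   order rule `ceil(3.3 fs / Δf)` rounded up to even gives orders 8250 and
   288 at 500 Hz), 0.5 s edge trimming, non-overlapping 6 s epochs.
2. **Artifact rejection** — per-(channel, epoch) peak amplitude, variance,
   mean |z|, and kurtosis; removal beyond 5 SD (peak, two-tailed) or 2.5 SD
   (the rest, upper tail); a dataset is retained only if at least one
   channel and more than five epochs survive.
3. **Spectral estimation** — DPSS multitaper power spectral density
   (±1 Hz smoothing, 11 tapers for 6 s epochs) on a 23-point log-spaced
   grid from 0.488 to 20.019 Hz (DFT bins of 500/4096 Hz).
4. **Aperiodic fit** — the exponent x of the `1/f^x` background by least
   squares of log10 power on log10 frequency; x = 0 is white noise, live
   planarians sit near 1.2–1.5, recordings of dead tissue near 2.7.
5. **Group statistics** — per-frequency label-permutation tests (10,000
   permutations, two-tailed, p floored at 1/n) with Benjamini–Yekutieli FDR
   correction across frequencies, and Welch t-tests on the fitted
   exponents.
6. **Synthetic recordings** — a fully seeded generator (power-law
   background via DFT amplitude shaping, band-limited oscillations,
   raised-cosine myogenic spikes, line-noise tones) so the whole chain is
   testable without any original data.

DPSS tapers are computed in-package from the tridiagonal Slepian
eigenproblem (Sturm bisection + inverse iteration), and recordings are read
and written as EDF or delimited text.

## Worked example

```r
library(planeeg)

cfg <- study_config(
  synthesis = synthesis_config(
    n_datasets_per_group = 6, duration = 300,
    exponent_per_group = c(darkness = 1.23, light = 1.31, control = 2.72),
    seed = 42),
  stats = stats_config(n_permutations = 2000, seed = 42))
report <- run_study(cfg)
print(report)
#> <study_report> 18 dataset(s), 18 retained
#>   control      n =  6  exponent 3.15 (SD 0.04)
#>   darkness     n =  6  exponent 1.32 (SD 0.02)
#>   light        n =  6  exponent 1.42 (SD 0.02)
#>   darkness_vs_light: 0/23 frequencies significant
#>   darkness_vs_control: 23/23 frequencies significant
#>   light_vs_control: 23/23 frequencies significant
```

Every recording survived rejection (the injected 50-SD spike epochs were
removed, not the datasets). The darkness and light groups are
indistinguishable per frequency after FDR correction, while both separate
from the steep-spectrum control group at every one of the 23 frequencies —
the qualitative pattern expected when live tissue is compared against a
dead-tissue control. The exponent contrast is decisive:

```r
report$comparisons$darkness_vs_control$exponent_test[c("t", "df", "p")]
#> $t
#> [1] -100.2629
#> $df
#> [1] 8.041731
#> $p
#> [1] 9.598388e-14

head(report$comparisons$darkness_vs_control$table, 4)
#>            freq        t      p significant
#> 0.488 0.4882812 19.55503 0.0015        TRUE
#> 0.610 0.6103516 19.10399 0.0015        TRUE
#> 0.732 0.7324219 18.81246 0.0015        TRUE
#> 0.854 0.8544922 20.41986 0.0015        TRUE
```

Note the fitted group means run slightly above the generator's target
exponents (3.15 vs 2.72 for the control group): ±1 Hz multitaper smoothing
cannot fully resolve a steep power law over the lowest octave of the grid,
so steep slopes are systematically inflated. The methods vignette
(`vignettes/planarian-eeg-methods.Rmd`) quantifies this estimator property
and its consequences.

With `output_dir` set, `run_study()` writes `spectra.csv`,
`exponents.csv`, one `comparison_<A>_vs_<B>.csv` per group pair (frequency,
t, permutation p, FDR flag — the layout of a published results table), and
a machine-readable `summary.json`. A YAML-driven command-line wrapper lives
in `inst/scripts/run_study.R`.

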