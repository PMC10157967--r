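test_that("the Hamming order rule reproduces both published filter orders", {
  hp <- design_fir(500, "highpass", 0.1, transition_bw = 0.2)
  lp <- design_fir(500, "lowpass", 23)              # default 0.25 x cutoff
  expect_identical(hp$order, 8250)
  expect_identical(lp$order, 288)
  expect_equal(lp$transition_bw, 5.75)
  ## defaults reproduce the same orders without explicit transition widths
  expect_identical(design_fir(500, "highpass", 0.1)$order, 8250)
})

test_that("designed filters are linear-phase with -6 dB at the cutoff", {
  for (spec in list(design_fir(500, "lowpass", 23),
                    design_fir(500, "highpass", 0.1),
                    design_fir(500, "notch", 50))) {
    expect_length(spec$h, spec$order + 1)
    expect_equal(spec$h, rev(spec$h))               # symmetric coefficients
  }
  lp <- design_fir(500, "lowpass", 23)
  db_at_cut <- 20 * log10(fir_response(lp, 23))
  expect_lt(abs(db_at_cut - (-6.02)), 0.5)
  hp <- design_fir(500, "highpass", 0.1)
  expect_lt(abs(20 * log10(fir_response(hp, 0.1)) - (-6.02)), 0.5)
  expect_error(design_fir(500, "lowpass", 260), "Nyquist")
})

test_that("two-pass filtering is zero-phase and behaves in pass/stop bands", {
  fs <- 500
  t <- (0:9999) / fs
  lp <- design_fir(fs, "lowpass", 23)
  ## 10 Hz passband sinusoid: unchanged phase, < 1% amplitude loss
  x <- sin(2 * pi * 10 * t)
  y <- filter_twopass(x, lp)
  mid <- 2000:8000
  expect_gt(max(abs(y[mid])), 0.99)
  expect_lt(max(abs(y[mid] - x[mid])), 0.02)        # no phase shift
  ## 50 Hz stopband sinusoid: two-pass attenuation >= 40 dB, confirmed both
  ## from the designed response and from the filtered waveform
  expect_lt(20 * log10(fir_response(lp, 50, two_pass = TRUE)), -40)
  z <- filter_twopass(sin(2 * pi * 50 * t), lp)
  expect_lt(20 * log10(max(abs(z[mid]))), -40)
  ## DC rejection by the high-pass: a 100 uV offset leaves < 0.01 uV
  ## (the Hamming design's stopband floor, doubled in dB by the two passes)
  hp <- design_fir(fs, "highpass", 0.1)
  d <- filter_twopass(rep(100, 20000), hp)
  expect_lt(max(abs(d)), 0.01)
  expect_lt(abs(mean(d)), 0.005)
})

test_that("two-pass filtering commutes with time reversal", {
  set.seed(4)
  x <- cumsum(rnorm(6000))
  lp <- design_fir(500, "lowpass", 23)
  expect_equal(filter_twopass(rev(x), lp), rev(filter_twopass(x, lp)),
               tolerance = 1e-9)
})

test_that("signals not longer than the filter order are rejected", {
  lp <- design_fir(500, "lowpass", 23)              # order 288
  expect_error(filter_twopass(rnorm(288), lp), "order")
  expect_silent(invisible(filter_twopass(rnorm(289), lp)))
})

test_that("trim-and-epoch arithmetic matches the segmentation rule", {
  fs <- 500
  cfg <- preprocess_config()
  ## 600 s -> floor(599 / 6) = 99 epochs
  r600 <- recording(matrix(rnorm(600 * fs), 1), fs)
  expect_equal(dim(trim_and_epoch(r600, cfg)$data)[1], 99)
  ## 13 s -> 2 epochs, remainder discarded
  r13 <- recording(matrix(rnorm(13 * fs), 1), fs)
  expect_equal(dim(trim_and_epoch(r13, cfg)$data)[1], 2)
  ## 6.9 s leaves 5.9 s after trimming: too short
  r69 <- recording(matrix(rnorm(3450), 1), fs)
  expect_error(trim_and_epoch(r69, cfg), "too short")
})

test_that("epoching tiles the trimmed signal losslessly", {
  fs <- 500
  x <- rnorm(13 * fs)
  ep <- trim_and_epoch(recording(x, fs), preprocess_config())
  trimmed <- x[(0.5 * fs + 1):(0.5 * fs + 2 * 6 * fs)]
  expect_identical(as.vector(t(ep$data[, 1, ])), trimmed)
})

test_that("the preprocessing chain runs end to end on multichannel data", {
  fs <- 500
  rec <- recording(matrix(rnorm(2 * 20 * fs), 2), fs, c("head", "tail"))
  ep <- preprocess_recording(rec, preprocess_config())
  expect_s3_class(ep, "epoch_set")
  expect_equal(dim(ep$data), c(3, 2, 3000))
  ## the wide-band notch crushes a 50 Hz tone (away from edge transients)
  t <- (0:(20 * fs - 1)) / fs
  tone <- sin(2 * pi * 50 * t)
  y <- filter_twopass(tone, design_fir(fs, "notch", 50))
  expect_lt(max(abs(y[4000:6000])), 1e-4)
  ## and passes neighbours outside the +/-2 Hz stop band untouched
  y44 <- filter_twopass(sin(2 * pi * 44 * t), design_fir(fs, "notch", 50))
  expect_gt(max(abs(y44[4000:6000])), 0.99)
  ## the full wide-band chain runs end to end
  cfg <- preprocess_config(lowpass = 110, notches = c(25, 50, 100))
  epn <- preprocess_recording(recording(rnorm(20 * fs), fs), cfg)
  expect_equal(dim(epn$data), c(3, 1, 3000))
})
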