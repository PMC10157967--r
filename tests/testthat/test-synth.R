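test_that("colored-noise generator recovers the target spectral slope", {
  ## independent oracle: least-squares fit of the raw log periodogram
  x <- generate_colored_noise(2^17, 500, 1.5, seed = 11)
  expect_equal(-periodogram_slope(x, 500), 1.5, tolerance = 0.1 / 1.5)

  ## white-noise identity case: flat log-log periodogram
  w <- generate_colored_noise(2^16, 500, 0, seed = 12)
  expect_lt(abs(periodogram_slope(w, 500)), 0.05)
})

test_that("spectral shaping is unbiased for x in {0, 1, 2}", {
  for (x_true in c(0, 1, 2)) {
    slopes <- vapply(1:50, function(s)
      -periodogram_slope(generate_colored_noise(2^15, 500, x_true,
                                                seed = 7000 + s), 500),
      numeric(1))
    expect_lt(abs(mean(slopes) - x_true), 0.05)
  }
})

test_that("generated background is standardized and seed-deterministic", {
  x <- generate_colored_noise(2^16, 500, 1.2, seed = 3)
  expect_lt(abs(mean(x)), 1e-12)
  expect_lt(abs(var(x) - 1), 0.01)
  expect_identical(x, generate_colored_noise(2^16, 500, 1.2, seed = 3))
  expect_false(identical(x, generate_colored_noise(2^16, 500, 1.2, seed = 4)))
  ## seeded calls leave the caller's RNG stream untouched
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_colored_noise(100, 500, 1, seed = 5))
  expect_identical(rnorm(3), before)
})

test_that("generator rejects degenerate arguments", {
  expect_error(generate_colored_noise(1, 500, 1), "n_samples")
  expect_error(generate_colored_noise(1000, 500, -0.5), "exponent")
  expect_error(generate_colored_noise(1000, 500, Inf), "exponent")
})

test_that("artifact injection is an identity when nothing is injected", {
  sig <- generate_colored_noise(10000, 500, 1, seed = 21)
  expect_identical(inject_artifacts(sig, 500, spike_rate = 0,
                                    line_noise = list()), sig)
})

test_that("line noise appears exactly at the injected frequency", {
  z <- inject_artifacts(numeric(5000), 500, 0, 0,
                        line_noise = list(c(50, 1)), seed = 2)
  P <- abs(fft(z))^2
  f <- (0:4999) * 500 / 5000
  expect_equal(f[which.max(P[1:2500])], 50)
  expect_error(inject_artifacts(numeric(100), 500, 0, 0,
                                line_noise = list(c(250, 1))), "Nyquist")
})

test_that("spike events have the configured count, width and magnitude", {
  sig <- generate_colored_noise(300000, 500, 1, seed = 31)
  out <- inject_artifacts(sig, 500, spike_rate = 6, spike_amplitude = 50,
                          seed = 32)
  ## count by thresholding at 25 SD: 6/min for 10 min = 60 events (a few may
  ## overlap into one threshold crossing)
  above <- abs(out) > 25 * sd(sig)
  clusters <- sum(diff(c(0, above)) == 1)
  expect_gte(clusters, 52)
  expect_lte(clusters, 60)
  ## each crossing shorter than 100 ms
  runs <- rle(above)
  expect_lt(max(runs$lengths[runs$values]) / 500, 0.1)
  ## on a silent background the transient peak equals the nominal amplitude
  ## (unit falls back to 1 uV at zero input SD)
  z <- inject_artifacts(numeric(50000), 500, spike_rate = 6,
                        spike_amplitude = 50, seed = 33)
  expect_equal(max(abs(z)), 50, tolerance = 1e-12)
})

test_that("simulated group studies are reproducible and well-labelled", {
  cfg <- synthesis_config(n_datasets_per_group = 2, duration = 10,
                          exponent_per_group = c(a = 1, b = 2), seed = 42,
                          spike_rate = 1, line_noise = list(c(50, 0.5)))
  s1 <- simulate_group_study(cfg)
  s2 <- simulate_group_study(cfg)
  expect_identical(s1$recordings, s2$recordings)
  expect_equal(nrow(s1$manifest), 4)
  expect_equal(s1$manifest$group, c("a", "a", "b", "b"))
  expect_true(all(s1$manifest$seed < 2^31))
  expect_equal(unname(vapply(s1$recordings, function(r) r$group,
                             character(1))),
               s1$manifest$group)
  ## different exponents separate in the raw periodogram slope already
  sa <- -periodogram_slope(s1$recordings[[1]]$data[1, ], 500, 1, 20)
  sb <- -periodogram_slope(s1$recordings[[3]]$data[1, ], 500, 1, 20)
  expect_lt(sa, sb)
})

test_that("synthesis config enforces Nyquist and group structure", {
  expect_error(synthesis_config(exponent_per_group = c(1, 2)), "named")
  expect_error(synthesis_config(exponent_per_group = c(a = -1, b = 2)),
               "finite")
  expect_error(synthesis_config(fs = 90, line_noise = list(c(50, 1))),
               "Nyquist")
  cfg <- synthesis_config(n_datasets_per_group = 2, duration = 5,
                          exponent_per_group = c(a = 1), seed = 1)
  expect_error(simulate_group_study(cfg), "two groups")
})
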