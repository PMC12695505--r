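test_that("Welch PSD integrates to the signal variance (Parseval)", {
  rec <- noise_recording(fs = 512, duration_s = 60, seed = 21)
  ps <- welch_psd(rec)
  df <- ps$freqs[2] - ps$freqs[1]
  expect_equal(sum(ps$power[1, ]) * df, var(as.vector(rec$data)),
               tolerance = 0.05)
  expect_equal(df, 1)                      # 1-s windows -> 1 Hz bins
  expect_true(all(ps$power >= 0))
})

test_that("a sinusoid peaks at its own frequency bin", {
  ps <- welch_psd(sine_recording(10, fs = 512, duration_s = 10))
  expect_equal(ps$freqs[which.max(ps$power[1, ])], 10)
  ps2 <- welch_psd(sine_recording(19, fs = 512, duration_s = 10),
                   window_s = 2)
  expect_equal(ps2$freqs[which.max(ps2$power[1, ])], 19)
})

test_that("degenerate welch inputs behave per contract", {
  zero <- eeg_recording(matrix(0, 1, 1024), fs = 512, channels = "Cz")
  expect_true(all(welch_psd(zero)$power == 0))
  short <- eeg_recording(matrix(rnorm(100), 1), fs = 512, channels = "Cz")
  expect_error(welch_psd(short), "shorter")
  expect_error(welch_psd(zero, overlap = 1), "overlap")
})

test_that("band powers on a flat spectrum equal height times bandwidth", {
  ps <- flat_spectrum(value = 2)
  bands <- qeeg_bands()
  for (i in seq_len(nrow(bands))) {
    expect_equal(unname(band_power(ps, bands$lo[i], bands$hi[i])),
                 2 * (bands$hi[i] - bands$lo[i]))
  }
  expect_error(band_power(ps, 300, 310, band = "bogus"), "bogus")
})

test_that("a 10 Hz tone lands almost entirely in alpha", {
  rel <- relative_band_power(welch_psd(sine_recording(10, duration_s = 60)))
  expect_gte(rel[1, "alpha"], 0.99)
})

test_that("equal two-tone signal splits between delta and beta", {
  t <- seq_len(512 * 60) / 512
  rec <- eeg_recording(matrix(sin(2 * pi * 2 * t) + sin(2 * pi * 20 * t), 1),
                       fs = 512, channels = "Cz")
  rel <- relative_band_power(welch_psd(rec))
  expect_equal(unname(rel[1, "delta"]), 0.5, tolerance = 0.02)
  expect_equal(unname(rel[1, "beta"]), 0.5, tolerance = 0.02)
  expect_lt(rel[1, "theta"] + rel[1, "alpha"], 0.02)
})

test_that("white-noise fractions approach the bandwidth ratios", {
  rel <- relative_band_power(welch_psd(noise_recording(duration_s = 120,
                                                       seed = 31)))
  expect_lt(max(abs(rel[1, ] - c(4, 4, 5, 17) / 30)), 0.02)
})

test_that("relative powers sum to one and are scale invariant", {
  for (seed in 1:5) {
    rec <- noise_recording(fs = 256, duration_s = 10,
                           channels = c("C3", "C4"), seed = seed)
    rel <- relative_band_power(welch_psd(rec))
    expect_equal(unname(rowSums(rel)), c(1, 1), tolerance = 1e-9)
    scaled <- rec
    scaled$data <- rec$data * (seed * 3.7)
    expect_equal(relative_band_power(welch_psd(scaled)), rel,
                 tolerance = 1e-9)
  }
})

test_that("relative alpha responds monotonically to an injected oscillator", {
  set.seed(41)
  base <- rnorm(256 * 30)
  t <- seq_along(base) / 256
  alphas <- vapply(c(0, 0.5, 1, 2), function(a) {
    rec <- eeg_recording(matrix(base + a * sin(2 * pi * 10 * t), 1),
                         fs = 256, channels = "Cz")
    relative_band_power(welch_psd(rec))[1, "alpha"]
  }, numeric(1))
  expect_true(all(diff(alphas) > 0))
  others <- vapply(c(0, 0.5, 1, 2), function(a) {
    rec <- eeg_recording(matrix(base + a * sin(2 * pi * 10 * t), 1),
                         fs = 256, channels = "Cz")
    sum(relative_band_power(welch_psd(rec))[1, c("delta", "theta", "beta")])
  }, numeric(1))
  expect_true(all(diff(others) < 0))
})

test_that("zero-power channels are reported by name", {
  rec <- eeg_recording(rbind(rnorm(1024), 0), fs = 512,
                       channels = c("C3", "C4"))
  expect_error(relative_band_power(welch_psd(rec)), "C4")
})

test_that("zone averages are unweighted means and preserve the sum", {
  m <- montage_32()
  rel <- matrix(0.25, 32, 4, dimnames = list(m$labels, qeeg_bands()$band))
  for (z in names(m$zones)) {
    expect_equal(unname(zone_average(rel, m, z)), rep(0.25, 4))
  }
  rel["C3", ] <- c(0.2, 0.2, 0.4, 0.2)
  rel["C4", ] <- c(0.4, 0.2, 0.2, 0.2)
  expect_equal(unname(zone_average(rel, m, "central")[c("delta", "alpha")]),
               c((0.2 + 0.4 + 0.25) / 3, (0.4 + 0.2 + 0.25) / 3))
  # random valid tables: zone values still sum to one across bands
  set.seed(17)
  for (i in 1:10) {
    raw <- matrix(rexp(32 * 4), 32, 4,
                  dimnames = list(m$labels, qeeg_bands()$band))
    raw <- raw / rowSums(raw)
    for (z in names(m$zones)) {
      expect_equal(sum(zone_average(raw, m, z)), 1, tolerance = 1e-9)
    }
  }
  expect_error(zone_average(rel[-1, ], m, "frontal"), "Fp1")
  expect_error(zone_average(rel, m, "nope"), "unknown zone")
})
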