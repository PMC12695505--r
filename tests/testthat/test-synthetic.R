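test_that("config invariants are enforced", {
  expect_error(cohort_config(group_sizes = c(A = 1, B = 5)), "at least 2")
  expect_error(cohort_config(noise_exponent = 0), "noise_exponent")
  expect_error(cohort_config(noise_exponent = 3), "noise_exponent")
  osc <- default_oscillators()
  osc$amplitude[1] <- -1
  expect_error(cohort_config(oscillators = osc), "non-negative")
})

test_that("pink band weights match numerical integration", {
  for (beta in c(0.5, 1, 1.7)) {
    w <- pink_band_weights(beta)
    oracle <- vapply(seq_len(4), function(i) {
      b <- qeeg_bands()
      lo <- max(b$lo[i], 0.5)
      stats::integrate(function(f) f^(-beta), lo, b$hi[i])$value
    }, numeric(1)) /
      stats::integrate(function(f) f^(-beta), 0.5, 40)$value
    expect_equal(unname(w), oracle, tolerance = 1e-6)
  }
})

test_that("recordings are reproducible and respect the spectral model", {
  cfg <- small_cohort_config()
  r1 <- generate_recording(cfg, seed = 77)
  r2 <- generate_recording(cfg, seed = 77)
  expect_identical(r1$data, r2$data)
  r3 <- generate_recording(cfg, seed = 78)
  expect_false(identical(r1$data, r3$data))
  expect_equal(r1$fs, 256)
  expect_equal(nrow(r1$data), 32)
  # alpha-dominant oscillator set shows up as alpha-dominant PSD
  rel <- relative_band_power(welch_psd(r1))
  expect_gt(mean(rel[, "alpha"]), mean(rel[, "theta"]))
  expect_error(generate_recording(cohort_config(duration_s = 1)), "2 s")
})

test_that("null configuration gives matched band powers across visits", {
  cfg <- cohort_config(group_sizes = c(CRB_sham = 60), within_sd = 0,
                       zone_sd = 0, seed = 88)
  model <- sample_cohort_band_powers(cfg)
  sub <- model$subjects
  for (b in qeeg_bands()$band) {
    v1 <- sub$relative_power[sub$band == b & sub$visit == "V1"]
    v2 <- sub$relative_power[sub$band == b & sub$visit == "V2"]
    expect_equal(v1, v2, tolerance = 1e-12)  # no within-subject change
  }
})

test_that("an injected delta amplitude increase raises relative delta", {
  effects <- matrix(1, 1, 4, dimnames = list("CRB_sham",
                                             qeeg_bands()$band))
  effects["CRB_sham", "delta"] <- 1.5
  cfg <- cohort_config(group_sizes = c(CRB_sham = 100), effects = effects,
                       within_sd = 0.05, seed = 89)
  sub <- sample_cohort_band_powers(cfg)$subjects
  d_v1 <- sub$relative_power[sub$band == "delta" & sub$visit == "V1"]
  d_v2 <- sub$relative_power[sub$band == "delta" & sub$visit == "V2"]
  expect_gt(mean(d_v2), mean(d_v1))
  expect_gt(mean(sign(d_v2 - d_v1)), 0.9)
  # and at the signal level on a handful of subjects
  amps <- stats::setNames(default_oscillators()$amplitude,
                          qeeg_bands()$band)
  small <- small_cohort_config()
  rel_base <- relative_band_power(welch_psd(
    generate_recording(small, amplitudes = amps, seed = 5)))
  amps2 <- amps
  amps2["delta"] <- amps2["delta"] * 1.5
  rel_up <- relative_band_power(welch_psd(
    generate_recording(small, amplitudes = amps2, seed = 5)))
  expect_gt(mean(rel_up[, "delta"]), mean(rel_base[, "delta"]))
})

test_that("scores track alpha positively and delta negatively", {
  sm <- default_score_model()
  sm$noise_sd <- 1e-9
  cfg <- cohort_config(group_sizes = c(CRB_sham = 40), score_model = sm,
                       missing_cantab = c(0, 0), seed = 90)
  ch <- generate_cohort(cfg, signals = FALSE)
  sub <- ch$subjects
  alpha <- sub$relative_power[sub$band == "alpha"]
  delta <- sub$relative_power[sub$band == "delta"]
  key <- paste(sub$subject_id[sub$band == "alpha"],
               sub$visit[sub$band == "alpha"])
  idx <- match(paste(ch$scores$subject_id, ch$scores$visit), key)
  # noiseless limit: MoCA is a deterministic increasing function of the
  # alpha/delta combination; against the latent combination rho = 1
  latent <- sm$weight_alpha * alpha[idx] + sm$weight_delta * delta[idx]
  expect_equal(suppressWarnings(cor(ch$scores$MoCA, latent,
                                    method = "spearman")), 1)
  # reaction-time-like tests run the other way
  expect_equal(suppressWarnings(cor(ch$scores$RTI, latent,
                                    method = "spearman")), -1)
})

test_that("CANTAB missingness bookkeeping matches the configured cells", {
  cfg <- cohort_config(group_sizes = c(CRB_rTMS = 16, CRB_sham = 15,
                                       PLC_sham = 19),
                       missing_cantab = c(2, 1), seed = 91)
  ch <- generate_cohort(cfg, signals = FALSE)
  n <- sum(cfg$group_sizes)
  for (test in c("RTI", "Multitasking", "OTS")) {
    expect_equal(sum(!is.na(ch$scores[[test]])), 2 * n - 3)
  }
  expect_equal(sum(!is.na(ch$scores$MoCA)), 2 * n)
  # the correlation layer sees exactly 2N - 3 complete pairs
  cells <- spearman_with_fdr(
    ch$band_powers[ch$band_powers$zone == "whole_scalp", ], ch$scores)
  expect_equal(unique(cells$n_pairs[cells$score == "RTI"]), 2 * n - 3)
  expect_equal(unique(cells$n_pairs[cells$score == "MoCA"]), 2 * n)
})

test_that("cohort generation is reproducible and writes readable files", {
  cfg <- small_cohort_config(seed = 92)
  dir <- withr::local_tempdir()
  c1 <- generate_cohort(cfg, signals = TRUE, dir = dir)
  c2 <- generate_cohort(cfg, signals = TRUE)
  expect_identical(c1$recordings[[1]]$data, c2$recordings[[1]]$data)
  expect_identical(c1$scores, c2$scores)
  md <- read_metadata(file.path(dir, "metadata.csv"))
  expect_equal(nrow(md), 2 * sum(cfg$group_sizes))
  first <- read_recording(
    file.path(dir, paste0(md$subject_id[1], "_", md$visit[1], ".csv")))
  expect_equal(first$fs, cfg$fs)
  expect_equal(nrow(first$data), 32)
})
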