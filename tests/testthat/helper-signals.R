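# Shared fixtures: deterministic toy recordings and cohorts built in code.

sine_recording <- function(freq, fs = 512, duration_s = 60, amp = 1,
                           channels = "Cz", phase = 0) {
  t <- seq_len(fs * duration_s) / fs
  data <- matrix(rep(amp * sin(2 * pi * freq * t + phase),
                     length(channels)),
                 nrow = length(channels), byrow = TRUE)
  eeg_recording(data, fs = fs, channels = channels)
}

noise_recording <- function(fs = 512, duration_s = 60, channels = "Cz",
                            seed = 1) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(fs * duration_s * length(channels)),
                       nrow = length(channels)),
                fs = fs, channels = channels)
}

# Hand-built flat power spectrum (for analytic band-power checks).
flat_spectrum <- function(value = 1, fmax = 256, channels = "Cz") {
  structure(list(freqs = 0:fmax,
                 power = matrix(value, length(channels), fmax + 1,
                                dimnames = list(channels, NULL)),
                 window_s = 1, overlap = 0.5, n_segments = 1),
            class = "power_spectrum")
}

# Small cohort config the whole-pipeline tests can run in seconds.
small_cohort_config <- function(...) {
  cohort_config(group_sizes = c(CRB_rTMS = 4, CRB_sham = 4, PLC_sham = 5),
                fs = 256, duration_s = 8, ...)
}

# Exhaustive Cliff's delta oracle: full pair enumeration.
cliffs_delta_oracle <- function(x, y) {
  mean(outer(x, y, function(xi, yj) sign(yj - xi)))
}

# Exact two-sided rank-sum p by enumerating all allocations of the
# combined sample (no ties assumed).
rank_sum_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  idx <- utils::combn(n, length(x))
  w_obs <- sum(rank(pooled)[seq_along(x)])
  ranks <- rank(pooled)
  ws <- apply(idx, 2, function(i) sum(ranks[i]))
  mu <- length(x) * (n + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Exact two-sided signed-rank p by enumerating all 2^n sign patterns.
signed_rank_exact_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9)
}
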