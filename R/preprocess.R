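# Signal-processing primitives: windowed-sinc FIR design, FFT convolution,
# polyphase resampling, IIR notch with zero-phase application.

# Symmetric lowpass FIR, Hamming window, cutoff in cycles/sample (0, 0.5).
fir_lowpass <- function(cutoff, n_taps) {
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1L
  m <- (n_taps - 1) / 2
  k <- -m:m
  h <- 2 * cutoff * sinc(2 * cutoff * k)
  w <- 0.54 + 0.46 * cos(pi * k / m)
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Zero-phase FIR filtering by FFT convolution with edge reflection.
fir_filtfilt <- function(x, h) {
  m <- (length(h) - 1) / 2
  n <- length(x)
  pad <- min(n - 1, length(h))
  xp <- c(2 * x[1] - x[pad:1 + 1], x, 2 * x[n] - x[n - (1:pad)])
  nfft <- stats::nextn(length(xp) + length(h) - 1, 2)
  y <- Re(stats::fft(stats::fft(c(xp, rep(0, nfft - length(xp)))) *
                     stats::fft(c(h, rep(0, nfft - length(h)))),
                     inverse = TRUE)) / nfft
  y[(pad + m + 1):(pad + m + n)]
}

# Biquad notch (RBJ cookbook), quality factor q.
notch_coefficients <- function(f0, fs, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Zero-phase IIR filtering (forward-backward) with odd-reflection padding.
# Narrowband filters ring at pad junctions; prefer iir_zero_phase for those.
iir_filtfilt <- function(x, b, a, pad = min(length(x) - 1, 3000L)) {
  n <- length(x)
  xp <- odd_reflect_pad(x, pad)
  y <- .iir_filter(b, a, xp)
  y <- rev(.iir_filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

odd_reflect_pad <- function(x, pad) {
  if (pad == 0) return(x)
  n <- length(x)
  c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
}

# Zero-phase application of an IIR filter's squared magnitude response in
# the frequency domain. State-free, so a high-Q notch leaves no edge
# transients; odd-reflection padding suppresses circular wrap-around.
iir_zero_phase <- function(x, b, a, pad = min(length(x) - 1, 3000L)) {
  n <- length(x)
  xp <- odd_reflect_pad(x, pad)
  m <- length(xp)
  w <- 2 * pi * (0:(m - 1)) / m
  z <- exp(-1i * w)
  h <- (b[1] + b[2] * z + b[3] * z^2) / (a[1] + a[2] * z + a[3] * z^2)
  y <- Re(stats::fft(stats::fft(xp) * Mod(h)^2, inverse = TRUE)) / m
  y[(pad + 1):(pad + n)]
}

# Polyphase-style resampling: upsample by L, windowed-sinc lowpass,
# downsample by M, where L/M = target_fs/fs reduced.
resample_signal <- function(x, fs, target_fs) {
  if (target_fs == fs) return(x)
  g <- gcd(round(target_fs * 1e6), round(fs * 1e6))
  l <- round(target_fs * 1e6) / g
  m <- round(fs * 1e6) / g
  n <- length(x)
  if (l > 1) {
    up <- numeric(n * l)
    up[seq(1, by = l, length.out = n)] <- x * l
  } else {
    up <- x
  }
  cutoff <- 0.5 / max(l, m) * 0.9
  n_taps <- 2L * as.integer(10 * max(l, m)) + 1L
  h <- fir_lowpass(cutoff, n_taps)
  y <- fir_filtfilt(up, h)
  y[seq(1, length(y), by = m)][seq_len(floor(n * l / m))]
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

#' Preprocess an EEG recording
#'
#' Applies the standard resting-state preprocessing contract: polyphase
#' downsampling to `target_fs`, re-referencing to the instantaneous average
#' of all channels, and a zero-phase second-order IIR notch (quality factor
#' 30) at `notch_hz`. A windowed-sinc band-pass can be re-applied for raw
#' inputs that were not band-limited at acquisition (`apply_bandpass`).
#'
#' @param rec An [eeg_recording()].
#' @param target_fs Target sampling rate in Hz (default 512); must not
#'   exceed the recording's rate (no upsampling).
#' @param notch_hz Power-line frequency to notch out (default 50 Hz);
#'   `NA` skips the notch.
#' @param bandpass Length-2 numeric, band edges in Hz (default
#'   `c(0.5, 40)`); only applied when `apply_bandpass = TRUE`.
#' @param apply_bandpass Re-apply the acquisition band-pass (default
#'   `FALSE`: treated as an acquisition property).
#' @param notch_q Notch quality factor (default 30).
#' @return A preprocessed [eeg_recording()] at `target_fs`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(4096), nrow = 2), fs = 1024,
#'                      channels = c("C3", "C4"))
#' pp <- preprocess(rec)
#' pp$fs
#' @export
preprocess <- function(rec, target_fs = 512, notch_hz = 50,
                       bandpass = c(0.5, 40), apply_bandpass = FALSE,
                       notch_q = 30) {
  if (target_fs > rec$fs) {
    stop("target_fs (", target_fs, ") exceeds recording rate (", rec$fs,
         "): upsampling is not supported")
  }
  if (nrow(rec$data) < 2) {
    stop("average reference undefined for fewer than 2 channels")
  }
  data <- rec$data
  if (target_fs < rec$fs) {
    data <- t(apply(data, 1, resample_signal, fs = rec$fs,
                    target_fs = target_fs))
  }
  fs <- target_fs
  # average reference: subtract the instantaneous cross-channel mean
  data <- sweep(data, 2, colMeans(data))
  if (!is.na(notch_hz)) {
    if (notch_hz >= fs / 2) stop("notch frequency must be below Nyquist")
    # circular (pad-free) application: a notch only alters the narrow
    # removed band, so wrap-around effects cannot leak outside it
    co <- notch_coefficients(notch_hz, fs, q = notch_q)
    data <- t(apply(data, 1, iir_zero_phase, b = co$b, a = co$a, pad = 0))
  }
  if (apply_bandpass) {
    if (bandpass[1] >= bandpass[2] || bandpass[2] >= fs / 2) {
      stop("bandpass edges must satisfy low < high < fs/2")
    }
    n_taps <- 2L * as.integer(2 * fs / bandpass[1]) + 1L
    h_lo <- fir_lowpass(bandpass[2] / fs, n_taps)
    h_hi_lo <- fir_lowpass(bandpass[1] / fs, n_taps)
    data <- t(apply(data, 1, function(ch) {
      fir_filtfilt(ch, h_lo) - fir_filtfilt(ch, h_hi_lo)
    }))
  }
  eeg_recording(data, fs = fs, channels = rec$channels,
                subject_id = rec$subject_id, group = rec$group,
                visit = rec$visit)
}
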