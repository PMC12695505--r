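#' Canonical EEG frequency bands
#'
#' Delta 0-4 Hz, theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz. The four
#' bands exactly partition the analysed 0-30 Hz spectrum; spectral bins
#' straddling a shared edge are split between the adjoining bands by the
#' overlap rule of [band_power()], so relative powers sum to one with no
#' double counting.
#'
#' @return A data.frame with columns `band`, `lo`, `hi`.
#' @export
qeeg_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta"),
             lo = c(0, 4, 8, 13), hi = c(4, 8, 13, 30),
             stringsAsFactors = FALSE)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)

#' Welch power spectral density
#'
#' One-sided PSD in physical units (microvolts squared per hertz) by
#' averaging Hann-tapered, constant-detrended periodograms over
#' overlapping segments.
#'
#' @param rec An [eeg_recording()].
#' @param window_s Segment length in seconds (default 1; the frequency
#'   resolution is `1/window_s` Hz).
#' @param overlap Overlap fraction in `[0, 1)` (default 0.5).
#' @param window Taper: `"hann"` (default) or `"rectangular"`.
#' @param detrend Per-segment detrending: `"constant"` (default, subtract
#'   the segment mean) or `"none"`.
#' @return An object of class `power_spectrum`: list with `freqs` (Hz),
#'   `power` (channels x frequencies, uV^2/Hz), `window_s`, `overlap`,
#'   `n_segments`.
#' @examples
#' rec <- eeg_recording(matrix(sin(2 * pi * 10 * (1:2560) / 512), 1),
#'                      fs = 512, channels = "Oz")
#' ps <- welch_psd(rec)
#' ps$freqs[which.max(ps$power[1, ])]  # 10 Hz peak
#' @export
welch_psd <- function(rec, window_s = 1, overlap = 0.5,
                      window = c("hann", "rectangular"),
                      detrend = c("constant", "none")) {
  window <- match.arg(window)
  detrend <- match.arg(detrend)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  n <- ncol(rec$data)
  len <- as.integer(round(window_s * rec$fs))
  if (n < len) stop("recording shorter than one analysis window")
  step <- max(1L, len - as.integer(round(len * overlap)))
  starts <- seq(1L, n - len + 1L, by = step)
  w <- if (window == "hann") hann_window(len) else rep(1, len)
  u <- sum(w^2)                       # window power normalization
  n_freq <- len %/% 2L + 1L
  freqs <- (seq_len(n_freq) - 1L) * rec$fs / len
  power <- matrix(0, nrow = nrow(rec$data), ncol = n_freq,
                  dimnames = list(rec$channels, NULL))
  for (s in starts) {
    seg <- rec$data[, s:(s + len - 1L), drop = FALSE]
    if (detrend == "constant") seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2, w, `*`)
    sp <- stats::mvfft(t(seg))[seq_len(n_freq), , drop = FALSE]
    pxx <- t(Mod(sp)^2) / (rec$fs * u)
    scale2 <- rep(2, n_freq)
    scale2[1] <- 1
    if (len %% 2L == 0L) scale2[n_freq] <- 1   # Nyquist bin not doubled
    power <- power + sweep(pxx, 2, scale2, `*`)
  }
  power <- power / length(starts)
  structure(list(freqs = freqs, power = power, window_s = window_s,
                 overlap = overlap, n_segments = length(starts)),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(paste0("Welch PSD: %d channels, %d bins (0-%g Hz, df = %g Hz),",
                     " %d segments\n"),
              nrow(x$power), length(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1], x$n_segments))
  invisible(x)
}

# Overlap weights: bin at centre f covers [f - df/2, f + df/2]; its
# weight in a band is the covered fraction of that interval, so bins on a
# shared band edge are split half/half and adjoining bands never double
# count.
band_bin_weights <- function(freqs, lo, hi) {
  df <- freqs[2] - freqs[1]
  pmax(0, (pmin(freqs + df / 2, hi) - pmax(freqs - df / 2, lo))) / df
}

#' Absolute band power
#'
#' Integral of the PSD over one frequency band, treating each spectral bin
#' as a rectangle of width `df` centred on its bin frequency: band power =
#' sum of bin power times the bin's overlap with `[lo, hi]`, times `df`.
#' A flat spectrum of height c therefore integrates to exactly
#' `c * (hi - lo)`, and bands sharing an edge split the straddling bin.
#'
#' @param ps A `power_spectrum`.
#' @param lo,hi Band edges in Hz.
#' @param band Band name used in error messages.
#' @return Named numeric vector, one absolute power (uV^2) per channel.
#' @export
band_power <- function(ps, lo, hi, band = NULL) {
  w <- band_bin_weights(ps$freqs, lo, hi)
  if (all(w == 0)) {
    stop("no spectral bins fall in band ",
         if (is.null(band)) sprintf("[%g, %g]", lo, hi) else band)
  }
  df <- ps$freqs[2] - ps$freqs[1]
  stats::setNames(as.vector(ps$power %*% w) * df, rownames(ps$power))
}

#' Relative band power per channel
#'
#' Per-channel fraction of 0-30 Hz power in each canonical band: each
#' electrode's band power divided by its total power over the analysed
#' spectrum. Fractions sum to exactly one across the four bands.
#'
#' @param ps A `power_spectrum`.
#' @param bands Band definition table (default [qeeg_bands()]).
#' @return Matrix channels x bands of fractions in `[0, 1]`.
#' @export
relative_band_power <- function(ps, bands = qeeg_bands()) {
  abs_power <- sapply(seq_len(nrow(bands)), function(i) {
    band_power(ps, bands$lo[i], bands$hi[i], band = bands$band[i])
  })
  abs_power <- matrix(abs_power, nrow = nrow(ps$power),
                      dimnames = list(rownames(ps$power), bands$band))
  total <- rowSums(abs_power)
  zero <- total <= 0
  if (any(zero)) {
    stop("zero total 0-30 Hz power on channel(s): ",
         paste(rownames(abs_power)[zero], collapse = ", "))
  }
  abs_power / total
}

#' Zone-averaged relative band power
#'
#' Unweighted arithmetic mean of per-electrode relative powers over the
#' electrodes of one scalp zone, per band. `whole_scalp` averages all 32.
#'
#' @param rel Channels x bands matrix from [relative_band_power()].
#' @param montage A [montage_32()].
#' @param zone Zone name (must exist in `montage$zones`).
#' @return Named numeric vector, one fraction per band.
#' @export
zone_average <- function(rel, montage, zone) {
  if (!zone %in% names(montage$zones)) stop("unknown zone: ", zone)
  members <- montage$zones[[zone]]
  absent <- setdiff(members, rownames(rel))
  if (length(absent) > 0) {
    stop("zone '", zone, "' electrodes missing from recording: ",
         paste(absent, collapse = ", "))
  }
  colMeans(rel[members, , drop = FALSE])
}

#' Build the long-format band-power table for a cohort
#'
#' Runs preprocessing, Welch PSD, relative band power and zone averaging
#' for each recording and stacks the results into the tidy table the
#' statistics layer consumes.
#'
#' @param recordings List of annotated [eeg_recording()] objects (subject,
#'   group, visit set).
#' @param montage A [montage_32()] (or any montage whose zones are subsets
#'   of the recordings' channels).
#' @param preprocess_args List of arguments for [preprocess()]; `NULL`
#'   skips preprocessing (inputs already clean).
#' @param window_s,overlap Welch parameters.
#' @return List with `zones`: data.frame (subject_id, group, visit, zone,
#'   band, relative_power), and `electrodes`: likewise with a `channel`
#'   column instead of `zone`.
#' @export
band_power_table <- function(recordings, montage = montage_32(),
                             preprocess_args = list(),
                             window_s = 1, overlap = 0.5) {
  zone_rows <- list()
  elec_rows <- list()
  for (rec in recordings) {
    if (!is.null(preprocess_args)) {
      rec <- do.call(preprocess, c(list(rec), preprocess_args))
    }
    ps <- welch_psd(rec, window_s = window_s, overlap = overlap)
    rel <- relative_band_power(ps)
    for (z in names(montage$zones)) {
      v <- zone_average(rel, montage, z)
      zone_rows[[length(zone_rows) + 1L]] <-
        data.frame(subject_id = rec$subject_id, group = rec$group,
                   visit = rec$visit, zone = z, band = names(v),
                   relative_power = unname(v), stringsAsFactors = FALSE)
    }
    elec_rows[[length(elec_rows) + 1L]] <-
      data.frame(subject_id = rec$subject_id, group = rec$group,
                 visit = rec$visit,
                 channel = rep(rownames(rel), times = ncol(rel)),
                 band = rep(colnames(rel), each = nrow(rel)),
                 relative_power = as.vector(rel), stringsAsFactors = FALSE)
  }
  list(zones = do.call(rbind, zone_rows),
       electrodes = do.call(rbind, elec_rows))
}
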