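# Synthetic cohort generator: 1/f ("pink") background EEG plus band-limited
# oscillators whose amplitudes carry group-by-visit effects, and cognitive
# scores monotonically linked to relative alpha (positively) and relative
# delta (negatively) power.

#' Synthetic cohort configuration
#'
#' The stated world of the generator: three treatment arms of 16/15/19
#' subjects recorded at two visits, 32-channel 10-20 montage at 1024 Hz,
#' eyes-closed resting profile (alpha-dominant oscillator set over a 1/f
#' background). Band-limited oscillators are realized as narrowband
#' Gaussian noise; subject, visit and zone variability act multiplicatively
#' on oscillator amplitudes (log-normal).
#'
#' @param group_sizes Named counts per arm (default `c(CRB_rTMS = 16,
#'   CRB_sham = 15, PLC_sham = 19)`, the trial's arm sizes).
#' @param fs Sampling rate in Hz (default 1024).
#' @param duration_s Recording length in seconds (default 60; clinical
#'   recordings are longer but 60 s is ample for 1-s Welch windows).
#' @param noise_exponent Spectral slope beta of the 1/f^beta background
#'   (default 1, the classic pink regime; must be in (0, 2]).
#' @param noise_amplitude RMS of the broadband background in microvolts
#'   (default 10).
#' @param oscillators Data.frame (band, centre, bandwidth, amplitude):
#'   centre frequency and bandwidth in Hz, base RMS amplitude in
#'   microvolts. Default: delta 2+-1 Hz at 6 uV, theta 6+-1 at 5, alpha
#'   10+-1.5 at 12 (eyes-closed dominance), beta 20+-4 at 4.
#' @param effects 3 x 4 matrix (group x band) of multiplicative amplitude
#'   change at visit 2 (default all 1: global null).
#' @param between_sd Between-subject SD of log amplitude (default 0.25).
#' @param within_sd Per-band visit-to-visit SD of log amplitude (default
#'   0.1 for each band); the probability that a band's amplitude rises at
#'   V2 is `pnorm(log(effect) / within_sd)`.
#' @param zone_sd Zone-level log-amplitude jitter at the band-power model
#'   level (default 0.05).
#' @param score_model List: `weight_alpha`, `weight_delta` (score units per
#'   unit relative power; defaults +40 and -40), `noise_sd` (default 2),
#'   and `tests`, a named direction vector (+1 = higher is better).
#' @param missing_cantab Integer length-2: number of subjects with missing
#'   CANTAB scores at V1 and V2 (default `c(2, 1)`).
#' @param seed Integer seed (default 20000523).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(CRB_rTMS = 16, CRB_sham = 15,
                                          PLC_sham = 19),
                          fs = 1024, duration_s = 60,
                          noise_exponent = 1, noise_amplitude = 10,
                          oscillators = default_oscillators(),
                          effects = NULL,
                          between_sd = 0.25,
                          within_sd = c(delta = 0.1, theta = 0.1,
                                        alpha = 0.1, beta = 0.1),
                          zone_sd = 0.05,
                          score_model = default_score_model(),
                          missing_cantab = c(2, 1),
                          seed = 20000523) {
  if (any(group_sizes < 2)) stop("group sizes must be at least 2")
  if (noise_exponent <= 0 || noise_exponent > 2) {
    stop("noise_exponent must be in (0, 2]")
  }
  if (any(oscillators$amplitude < 0)) stop("amplitudes must be non-negative")
  if (is.null(effects)) {
    effects <- matrix(1, nrow = length(group_sizes), ncol = 4,
                      dimnames = list(names(group_sizes),
                                      c("delta", "theta", "alpha", "beta")))
  }
  structure(list(group_sizes = group_sizes, fs = fs,
                 duration_s = duration_s,
                 noise_exponent = noise_exponent,
                 noise_amplitude = noise_amplitude,
                 oscillators = oscillators, effects = effects,
                 between_sd = between_sd, within_sd = within_sd,
                 zone_sd = zone_sd, score_model = score_model,
                 missing_cantab = missing_cantab, seed = seed),
            class = "cohort_config")
}

default_oscillators <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta"),
             centre = c(2, 6, 10, 20),
             bandwidth = c(2, 2, 3, 8),
             amplitude = c(6, 5, 12, 4),
             stringsAsFactors = FALSE)
}

default_score_model <- function() {
  list(weight_alpha = 40, weight_delta = -40, noise_sd = 2,
       tests = c(MoCA = 1, Stroop1 = -1, Stroop2 = -1, Stroop3 = -1,
                 DigitSpan = 1, PSI = 1, TMT = -1, HAMA = -1, HAMD = -1,
                 RTI = -1, Multitasking = -1, OTS = 1),
       cantab = c("RTI", "Multitasking", "OTS"))
}

# Fraction of 1/f^beta background power falling in each band, over the
# acquisition passband [0.5, 40] Hz, restricted to the analysed 0-30 Hz.
pink_band_weights <- function(beta, bands = qeeg_bands(),
                              passband = c(0.5, 40)) {
  seg <- function(lo, hi) {
    lo <- max(lo, passband[1]); hi <- min(hi, passband[2])
    if (hi <= lo) return(0)
    if (abs(beta - 1) < 1e-12) log(hi / lo)
    else (hi^(1 - beta) - lo^(1 - beta)) / (1 - beta)
  }
  total <- seg(passband[1], passband[2])
  vapply(seq_len(nrow(bands)), function(i) seg(bands$lo[i], bands$hi[i]),
         numeric(1)) / total
}

#' Sample the cohort's band-power model
#'
#' Draws the generator's latent amplitude structure and returns the
#' implied zone-level relative band powers directly, without synthesizing
#' any time series. This is the generative model the time-series path
#' realizes; it is used for fast calibration studies and drives the score
#' model.
#'
#' @param config A [cohort_config()].
#' @param seed Overrides `config$seed` when given.
#' @return List: `zones` — long data.frame (subject_id, group, visit,
#'   zone, band, relative_power); `subjects` — per subject-visit
#'   whole-scalp relative powers plus the latent band amplitudes (used by
#'   [generate_recording()] and the score model).
#' @export
sample_cohort_band_powers <- function(config, seed = NULL) {
  if (!is.null(seed)) config$seed <- seed
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  bands <- qeeg_bands()$band
  groups <- names(config$group_sizes)
  montage <- montage_32()
  zone_names <- setdiff(names(montage$zones), "whole_scalp")
  zone_n <- vapply(montage$zones[zone_names], length, integer(1))
  pink_w <- pink_band_weights(config$noise_exponent)
  names(pink_w) <- bands
  base_amp <- stats::setNames(config$oscillators$amplitude,
                              config$oscillators$band)[bands]
  within_sd <- rep(config$within_sd, length.out = 4)
  names(within_sd) <- bands

  subj_rows <- list(); zone_rows <- list()
  sid <- 0L
  for (g in groups) {
    for (i in seq_len(config$group_sizes[[g]])) {
      sid <- sid + 1L
      id <- sprintf("S%03d", sid)
      u <- stats::rnorm(4, 0, config$between_sd)         # subject trait
      u_noise <- stats::rnorm(1, 0, config$between_sd)
      noise_amp <- config$noise_amplitude * exp(u_noise)
      for (v in c("V1", "V2")) {
        shift <- if (v == "V2") {
          log(config$effects[g, bands]) + stats::rnorm(4, 0, within_sd)
        } else rep(0, 4)
        amp <- base_amp * exp(u + shift)
        abs_power <- amp^2 + noise_amp^2 * pink_w
        rel <- abs_power / sum(abs_power)
        subj_rows[[length(subj_rows) + 1L]] <-
          data.frame(subject_id = id, group = g, visit = v,
                     band = bands, amplitude = unname(amp),
                     noise_amplitude = noise_amp,
                     relative_power = unname(rel),
                     stringsAsFactors = FALSE)
        # zone level: multiplicative jitter on absolute powers, then
        # renormalize per zone; whole scalp = electrode-weighted mean
        rel_z <- matrix(NA_real_, nrow = length(zone_names), ncol = 4,
                        dimnames = list(zone_names, bands))
        for (z in zone_names) {
          abs_z <- abs_power * exp(stats::rnorm(4, 0, config$zone_sd))
          rel_z[z, ] <- abs_z / sum(abs_z)
        }
        whole <- colSums(rel_z * zone_n) / sum(zone_n)
        zone_rows[[length(zone_rows) + 1L]] <-
          data.frame(subject_id = id, group = g, visit = v,
                     zone = rep(c(zone_names, "whole_scalp"), each = 4),
                     band = rep(bands, length(zone_names) + 1L),
                     relative_power = c(t(rel_z), whole),
                     stringsAsFactors = FALSE)
      }
    }
  }
  list(zones = do.call(rbind, zone_rows),
       subjects = do.call(rbind, subj_rows))
}

# Gaussian noise spectrally shaped by magnitude response mag (length
# n %/% 2 + 1, one-sided), returned with unit RMS.
shaped_noise <- function(n, fs, mag) {
  x <- stats::rnorm(n)
  xf <- stats::fft(x)
  n_half <- n %/% 2 + 1
  h <- numeric(n)
  h[seq_len(n_half)] <- mag
  if (n %% 2 == 0) h[seq(n_half + 1, n)] <- rev(mag[2:(n_half - 1)])
  else h[seq(n_half + 1, n)] <- rev(mag[2:n_half])
  y <- Re(stats::fft(xf * h, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) y else y / s
}

#' Generate one synthetic EEG recording
#'
#' Each channel is an independent realization of the same spectral model:
#' 1/f^beta background (band-limited to the acquisition passband) plus one
#' narrowband Gaussian oscillator per band, with per-channel random phase.
#' Amplitudes default to the configured base values; pass the latent
#' amplitudes from [sample_cohort_band_powers()] to realize a specific
#' subject-visit.
#'
#' @param config A [cohort_config()].
#' @param subject_id,group,visit Annotations for the recording.
#' @param amplitudes Named per-band RMS amplitudes in microvolts (default:
#'   the configured base amplitudes).
#' @param noise_amplitude Background RMS (default: configured value).
#' @param seed Integer seed; each (seed) gives byte-identical output.
#' @param channels Channel labels (default: the 32-electrode montage).
#' @return An [eeg_recording()] at `config$fs`.
#' @export
generate_recording <- function(config, subject_id = NA_character_,
                               group = NA_character_,
                               visit = NA_character_,
                               amplitudes = NULL, noise_amplitude = NULL,
                               seed = config$seed,
                               channels = montage_32()$labels) {
  if (config$duration_s < 2) stop("duration must be at least 2 s")
  n <- as.integer(round(config$duration_s * config$fs))
  fs <- config$fs
  bands <- qeeg_bands()$band
  if (is.null(amplitudes)) {
    amplitudes <- stats::setNames(config$oscillators$amplitude,
                                  config$oscillators$band)
  }
  if (is.null(noise_amplitude)) noise_amplitude <- config$noise_amplitude
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  n_half <- n %/% 2 + 1
  freqs <- (seq_len(n_half) - 1) * fs / n
  # background magnitude: f^(-beta/2) inside the passband, 0 outside
  mag_bg <- ifelse(freqs >= 0.5 & freqs <= 40,
                   pmax(freqs, 0.5)^(-config$noise_exponent / 2), 0)
  osc <- config$oscillators
  mag_osc <- lapply(seq_len(nrow(osc)), function(i) {
    lo <- max(osc$centre[i] - osc$bandwidth[i] / 2, 1e-6)
    hi <- osc$centre[i] + osc$bandwidth[i] / 2
    as.numeric(freqs >= lo & freqs <= hi)
  })
  names(mag_osc) <- osc$band
  data <- matrix(0, nrow = length(channels), ncol = n,
                 dimnames = list(channels, NULL))
  for (ch in seq_along(channels)) {
    sig <- noise_amplitude * shaped_noise(n, fs, mag_bg)
    for (b in bands) {
      if (amplitudes[[b]] > 0) {
        sig <- sig + amplitudes[[b]] * shaped_noise(n, fs, mag_osc[[b]])
      }
    }
    data[ch, ] <- sig
  }
  eeg_recording(data, fs = fs, channels = channels,
                subject_id = subject_id, group = group, visit = visit)
}

#' Generate a full synthetic cohort
#'
#' Samples the band-power model for every subject and visit, derives the
#' neuropsychological scores from each subject-visit's realized whole-scalp
#' relative alpha and delta powers (linear model plus Gaussian noise, each
#' test on its natural direction), applies the configured CANTAB
#' missingness, and optionally realizes and/or writes the EEG time series.
#'
#' @param config A [cohort_config()].
#' @param seed Overrides `config$seed`.
#' @param signals Realize EEG time series (default `TRUE`; `FALSE` returns
#'   only the model-level band powers, metadata and scores).
#' @param dir When given, writes recordings in the matrix dialect plus
#'   `metadata.csv` and `scores.csv` into `dir`.
#' @return List: `metadata`, `scores`, `band_powers` (model-level zone
#'   table), `subjects` (latent amplitudes), `recordings` (named list, or
#'   NULL), `config`.
#' @export
generate_cohort <- function(config, seed = NULL, signals = TRUE,
                            dir = NULL) {
  if (!is.null(seed)) config$seed <- seed
  model <- sample_cohort_band_powers(config)
  subj <- model$subjects
  meta <- unique(subj[, c("subject_id", "group", "visit")])
  if (anyDuplicated(meta)) stop("duplicate subject id / visit combination")
  rownames(meta) <- NULL

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed + 1L)  # distinct stream for scores and signals

  sm <- config$score_model
  scores <- meta
  rel_alpha <- subj$relative_power[subj$band == "alpha"]
  rel_delta <- subj$relative_power[subj$band == "delta"]
  key_sub <- paste(subj$subject_id[subj$band == "alpha"],
                   subj$visit[subj$band == "alpha"])
  idx <- match(paste(meta$subject_id, meta$visit), key_sub)
  latent <- sm$weight_alpha * rel_alpha[idx] +
    sm$weight_delta * rel_delta[idx]
  for (test in names(sm$tests)) {
    scores[[test]] <- sm$tests[[test]] * latent +
      stats::rnorm(nrow(meta), 0, sm$noise_sd)
  }
  # CANTAB missingness: first k1 subjects lack V1 CANTAB, next k2 lack V2
  ids <- unique(meta$subject_id)
  k1 <- config$missing_cantab[1]; k2 <- config$missing_cantab[2]
  miss_v1 <- ids[seq_len(min(k1, length(ids)))]
  miss_v2 <- ids[k1 + seq_len(min(k2, max(0, length(ids) - k1)))]
  for (test in sm$cantab) {
    scores[[test]][scores$subject_id %in% miss_v1 & scores$visit == "V1"] <- NA
    scores[[test]][scores$subject_id %in% miss_v2 & scores$visit == "V2"] <- NA
  }

  recordings <- NULL
  if (signals) {
    recordings <- vector("list", nrow(meta))
    names(recordings) <- paste(meta$subject_id, meta$visit, sep = "_")
    for (r in seq_len(nrow(meta))) {
      rows <- subj$subject_id == meta$subject_id[r] &
        subj$visit == meta$visit[r]
      amp <- stats::setNames(subj$amplitude[rows], subj$band[rows])
      rec_seed <- (config$seed + 7L * r) %% .Machine$integer.max
      recordings[[r]] <- generate_recording(
        config, subject_id = meta$subject_id[r], group = meta$group[r],
        visit = meta$visit[r], amplitudes = amp,
        noise_amplitude = subj$noise_amplitude[rows][1], seed = rec_seed)
    }
  }
  out <- list(metadata = meta, scores = scores,
              band_powers = model$zones, subjects = subj,
              recordings = recordings, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
    utils::write.csv(scores, file.path(dir, "scores.csv"), row.names = FALSE)
    if (signals) {
      for (nm in names(recordings)) {
        write_recording(recordings[[nm]],
                        file.path(dir, paste0(nm, ".csv")), "matrix")
      }
    }
    utils::write.csv(model$zones, file.path(dir, "band_powers_model.csv"),
                     row.names = FALSE)
  }
  out
}
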