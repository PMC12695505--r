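#' EEG recording container
#'
#' A channels-by-samples block of EEG signal in microvolts, with sampling
#' rate, electrode labels and optional cohort annotations (subject id,
#' treatment group, visit).
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz (> 0).
#' @param channels Character vector of channel labels, one per data row,
#'   unique. Defaults to the rownames of `data`.
#' @param subject_id,group,visit Optional annotations. `group` must be one
#'   of `"CRB_rTMS"`, `"CRB_sham"`, `"PLC_sham"` when given; `visit` one of
#'   `"V1"`, `"V2"`.
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2048), nrow = 2), fs = 1024,
#'                      channels = c("C3", "C4"))
#' rec
#' @export
eeg_recording <- function(data, fs, channels = rownames(data),
                          subject_id = NA_character_,
                          group = NA_character_, visit = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  if (is.null(channels)) {
    channels <- paste0("ch", seq_len(nrow(data)))
  }
  channels <- as.character(channels)
  if (length(channels) != nrow(data)) {
    stop("number of channel labels (", length(channels),
         ") must equal number of data rows (", nrow(data), ")")
  }
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  if (!is.na(group)) {
    group <- match.arg(group, c("CRB_rTMS", "CRB_sham", "PLC_sham"))
  }
  if (!is.na(visit)) visit <- match.arg(visit, c("V1", "V2"))
  rownames(data) <- channels
  structure(list(data = data, fs = fs, channels = channels,
                 subject_id = subject_id, group = group, visit = visit),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.na(x$subject_id)) {
    cat(sprintf("  subject %s, group %s, visit %s\n",
                x$subject_id, x$group, x$visit))
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Length of the recording in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

infer_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         vhdr = "brainvision", eeg = "brainvision", vmrk = "brainvision",
         edf = "edf",
         "matrix")
}

#' Read an EEG recording
#'
#' Supported dialects: the BrainVision triplet (`.vhdr` ASCII header,
#' `.eeg` binary data, `.vmrk` markers), EDF, and a plain-text matrix
#' dialect for fixtures (one header line `fs,label1,label2,...`, then one
#' sample per row, comma separated, microvolts). Channel labels are
#' normalized to canonical 10-20 spelling where recognized; unknown labels
#' are kept with a warning.
#'
#' @param path File path (for BrainVision, the `.vhdr` member).
#' @param dialect One of `"auto"`, `"matrix"`, `"brainvision"`, `"edf"`.
#'   `"auto"` infers from the file extension.
#' @param normalize_labels Normalize channel labels to canonical 10-20
#'   spelling (default `TRUE`).
#' @return An [eeg_recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path,
                           dialect = c("auto", "matrix", "brainvision", "edf"),
                           normalize_labels = TRUE) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") dialect <- infer_dialect(path)
  if (!file.exists(path)) stop("file not found: ", path)
  rec <- switch(dialect,
                matrix = read_matrix_dialect(path),
                brainvision = read_brainvision(path),
                edf = read_edf(path))
  if (normalize_labels) {
    rec$channels <- normalize_channel_labels(rec$channels)
    rownames(rec$data) <- rec$channels
  }
  rec
}

#' Write an EEG recording
#'
#' @param rec An [eeg_recording()].
#' @param path Output path; for BrainVision the `.vhdr` path (the `.eeg`
#'   and `.vmrk` companions are written next to it).
#' @param dialect One of `"matrix"`, `"brainvision"`, `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path,
                            dialect = c("matrix", "brainvision", "edf")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         matrix = write_matrix_dialect(rec, path),
         brainvision = write_brainvision(rec, path),
         edf = write_edf(rec, path))
  invisible(path)
}

## ---- matrix dialect ----

read_matrix_dialect <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  fs <- suppressWarnings(as.numeric(header[1]))
  if (is.na(fs)) stop("matrix dialect: first header field must be the sampling rate")
  labels <- header[-1]
  m <- utils::read.table(path, sep = ",", skip = 1L,
                         colClasses = "numeric",
                         col.names = labels, check.names = FALSE)
  eeg_recording(t(as.matrix(m)), fs = fs, channels = labels)
}

write_matrix_dialect <- function(rec, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c(format(rec$fs), rec$channels), collapse = ","), con)
  utils::write.table(format(t(rec$data), digits = 9, trim = TRUE,
                            scientific = FALSE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

## ---- BrainVision triplet ----
## Minimal writer/reader: multiplexed IEEE_FLOAT_32, unit uV, ASCII header.

companion_paths <- function(vhdr_path) {
  base <- sub("\\.vhdr$", "", vhdr_path)
  list(vhdr = vhdr_path, eeg = paste0(base, ".eeg"),
       vmrk = paste0(base, ".vmrk"))
}

read_brainvision <- function(vhdr_path) {
  p <- companion_paths(vhdr_path)
  for (member in c("vhdr", "eeg", "vmrk")) {
    if (!file.exists(p[[member]])) {
      stop("BrainVision triplet incomplete: missing ", p[[member]])
    }
  }
  lines <- readLines(p$vhdr, warn = FALSE)
  getval <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (length(hit) == 0) stop("BrainVision header missing key: ", key)
    sub(paste0("^", key, "="), "", hit[1])
  }
  n_ch <- as.integer(getval("NumberOfChannels"))
  interval_us <- as.numeric(getval("SamplingInterval"))
  fs <- 1e6 / interval_us
  fmt <- getval("BinaryFormat")
  if (fmt != "IEEE_FLOAT_32") stop("unsupported BinaryFormat: ", fmt)
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_idx <- as.integer(sub("^Ch([0-9]+)=.*$", "\\1", ch_lines))
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",", fixed = TRUE)
  labels <- vapply(parts, `[`, character(1), 1L)[order(ch_idx)]
  scale <- vapply(parts, function(q) {
    s <- suppressWarnings(as.numeric(q[3]))
    if (is.na(s)) 1 else s
  }, numeric(1))[order(ch_idx)]
  raw <- readBin(p$eeg, what = "numeric", size = 4L,
                 n = file.size(p$eeg) / 4L, endian = "little")
  n_samp <- length(raw) %/% n_ch
  data <- matrix(raw[seq_len(n_ch * n_samp)], nrow = n_ch) * scale
  eeg_recording(data, fs = fs, channels = labels)
}

write_brainvision <- function(rec, vhdr_path) {
  p <- companion_paths(vhdr_path)
  n_ch <- nrow(rec$data)
  header <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "", "[Common Infos]",
    paste0("DataFile=", basename(p$eeg)),
    paste0("MarkerFile=", basename(p$vmrk)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_ch),
    paste0("SamplingInterval=", format(1e6 / rec$fs, scientific = FALSE)),
    "", "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(n_ch), rec$channels))
  writeLines(header, p$vhdr)
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "", "[Common Infos]",
               paste0("DataFile=", basename(p$eeg)),
               "", "[Marker Infos]",
               "Mk1=New Segment,,1,1,0"), p$vmrk)
  con <- file(p$eeg, open = "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 4L, endian = "little")
}

## ---- EDF ----
## Single-file European Data Format: 16-bit samples, 1-second data records.
## Round-trip is quantized (16-bit), unlike the float formats.

pad_str <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  n_ch <- nrow(rec$data)
  record_s <- 1
  spr <- as.integer(round(rec$fs * record_s))  # samples per record per channel
  n_rec <- floor(ncol(rec$data) / spr)
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  used <- rec$data[, seq_len(n_rec * spr), drop = FALSE]
  phys_min <- apply(used, 1, min)
  phys_max <- apply(used, 1, max)
  flat <- phys_max - phys_min < .Machine$double.eps
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768; dig_max <- 32767
  header_bytes <- 256L + 256L * n_ch
  con <- file(path, open = "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_str(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(header_bytes, 8); wr("", 44); wr(n_rec, 8); wr(record_s, 8); wr(n_ch, 4)
  for (lb in rec$channels) wr(lb, 16)
  for (i in seq_len(n_ch)) wr("EEG", 80)
  for (i in seq_len(n_ch)) wr("uV", 8)
  for (i in seq_len(n_ch)) wr(format(phys_min[i], digits = 7), 8)
  for (i in seq_len(n_ch)) wr(format(phys_max[i], digits = 7), 8)
  for (i in seq_len(n_ch)) wr(dig_min, 8)
  for (i in seq_len(n_ch)) wr(dig_max, 8)
  for (i in seq_len(n_ch)) wr("", 80)
  for (i in seq_len(n_ch)) wr(spr, 8)
  gain <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(n_ch)) {
      dig <- round((used[i, cols] - phys_min[i]) * gain[i] + dig_min)
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2L, endian = "little")
    }
  }
}

read_edf <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  record_s <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  labels <- vapply(seq_len(n_ch), function(i) rd(16), character(1))
  for (i in seq_len(n_ch)) rd(80)
  for (i in seq_len(n_ch)) rd(8)
  phys_min <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), numeric(1))
  phys_max <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), numeric(1))
  dig_min <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), numeric(1))
  dig_max <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(n_ch)) rd(80)
  spr <- vapply(seq_len(n_ch), function(i) as.integer(rd(8)), integer(1))
  if (length(unique(spr)) != 1L) stop("EDF: heterogeneous sampling rates unsupported")
  fs <- spr[1] / record_s
  data <- matrix(0, nrow = n_ch, ncol = n_rec * spr[1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (i in seq_len(n_ch)) {
      dig <- readBin(con, what = "integer", n = spr[1], size = 2L,
                     signed = TRUE, endian = "little")
      data[i, cols] <- (dig - dig_min[i]) * gain[i] + phys_min[i]
    }
  }
  eeg_recording(data, fs = fs, channels = labels)
}

## ---- tabular metadata ----

#' Read the subject metadata table
#'
#' CSV with required columns `subject_id`, `group`, `visit`. Group must be
#' one of `CRB_rTMS`, `CRB_sham`, `PLC_sham`; visit `V1` or `V2`.
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "visit")
  miss <- setdiff(need, names(md))
  if (length(miss) > 0) {
    stop("metadata missing required column(s): ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(md$group), c("CRB_rTMS", "CRB_sham", "PLC_sham"))
  if (length(bad) > 0) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(md$visit), c("V1", "V2"))
  if (length(bad) > 0) stop("unknown visit label(s): ", paste(bad, collapse = ", "))
  md
}

#' Read the neuropsychological score table
#'
#' CSV with columns `subject_id`, `visit` and one column per test; missing
#' cells are allowed (empty or NA).
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_scores <- function(path) {
  sc <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "visit")
  miss <- setdiff(need, names(sc))
  if (length(miss) > 0) {
    stop("score table missing required column(s): ", paste(miss, collapse = ", "))
  }
  sc
}
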