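#' The 32-electrode 10-20 montage and its scalp zones
#'
#' Construct the standard 32-channel 10-20 montage used throughout the
#' package, with electrodes grouped into named scalp zones (frontal,
#' central, parietal, temporal, occipital) plus `whole_scalp`, which is
#' always the full set of 32 labels. The default zone assignment ships as
#' a JSON file under `extdata/` and can be overridden with any mapping
#' whose labels are a subset of the 32.
#'
#' @param zone_file Path to a JSON file mapping zone name -> character
#'   vector of electrode labels. `NULL` uses the packaged default.
#' @return An object of class `montage32` with elements `labels` (the 32
#'   canonical electrode names) and `zones` (named list of label subsets,
#'   including `whole_scalp`).
#' @examples
#' m <- montage_32()
#' m$zones$central
#' @export
montage_32 <- function(zone_file = NULL) {
  labels <- c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz",
              "C3", "C4", "Cz", "P3", "P4", "P7", "P8", "Pz",
              "O1", "O2", "Oz", "FC1", "FC2", "FC5", "FC6",
              "CP1", "CP2", "CP5", "CP6", "T7", "T8",
              "TP9", "TP10", "PO9", "PO10")
  if (is.null(zone_file)) {
    zone_file <- system.file("extdata", "zones_1020.json", package = "qeegr")
  }
  zones <- jsonlite::read_json(zone_file, simplifyVector = TRUE)
  zones <- lapply(zones, as.character)
  bad <- setdiff(unlist(zones), labels)
  if (length(bad) > 0) {
    stop("zone file references unknown electrode label(s): ",
         paste(bad, collapse = ", "))
  }
  zones$whole_scalp <- labels
  structure(list(labels = labels, zones = zones), class = "montage32")
}

#' @export
print.montage32 <- function(x, ...) {
  cat("10-20 montage:", length(x$labels), "electrodes,",
      length(x$zones), "zones\n")
  for (z in names(x$zones)) {
    cat(sprintf("  %-12s %s\n", z, paste(x$zones[[z]], collapse = " ")))
  }
  invisible(x)
}

# Canonical spelling lookup: case-folded plus legacy 10-20 aliases
# (T3/T4 -> T7/T8, T5/T6 -> P7/P8).
normalize_channel_labels <- function(labels, canonical = montage_32()$labels) {
  aliases <- c(T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8")
  out <- vapply(labels, function(lb) {
    lb_trim <- trimws(lb)
    hit <- match(toupper(lb_trim), toupper(canonical))
    if (!is.na(hit)) return(canonical[hit])
    ali <- match(toupper(lb_trim), names(aliases))
    if (!is.na(ali)) return(unname(aliases[ali]))
    warning("unknown channel label kept as-is: ", lb_trim, call. = FALSE)
    lb_trim
  }, character(1), USE.NAMES = FALSE)
  out
}
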