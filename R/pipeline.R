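#' Analysis configuration
#'
#' Bundles every tunable of the end-to-end analysis: preprocessing
#' (target rate, notch), Welch parameters, ANOVA resampling iterations and
#' seed, the significance level, and the zone map.
#'
#' @param target_fs,notch_hz Preprocessing (see [preprocess()]).
#' @param window_s,overlap Welch parameters (see [welch_psd()]).
#' @param n_iter,seed Resampling ANOVA contract (defaults 10000 and
#'   20000523).
#' @param alpha Significance level in (0, 1) (default 0.05).
#' @param collapse_threshold Adjusted-p threshold for the collapsed
#'   correlation view (default 0.1).
#' @param zone_file Optional zone-map JSON override (see [montage_32()]).
#' @param preprocess Apply preprocessing to recordings (default `TRUE`;
#'   set `FALSE` for already-clean fixtures).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(target_fs = 512, notch_hz = 50,
                            window_s = 1, overlap = 0.5,
                            n_iter = 10000, seed = 20000523,
                            alpha = 0.05, collapse_threshold = 0.1,
                            zone_file = NULL, preprocess = TRUE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(target_fs = target_fs, notch_hz = notch_hz,
                 window_s = window_s, overlap = overlap,
                 n_iter = n_iter, seed = seed, alpha = alpha,
                 collapse_threshold = collapse_threshold,
                 zone_file = zone_file, preprocess = preprocess),
            class = "analysis_config")
}

#' Read an analysis or cohort configuration from JSON
#'
#' @param path JSON file; top-level keys are passed to [analysis_config()]
#'   or [cohort_config()].
#' @param type `"analysis"` or `"cohort"`.
#' @return The corresponding config object.
#' @export
read_config <- function(path, type = c("analysis", "cohort")) {
  type <- match.arg(type)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  fn <- if (type == "analysis") analysis_config else cohort_config
  if (type == "cohort") {
    if (!is.null(raw$oscillators)) {
      raw$oscillators <- as.data.frame(raw$oscillators)
    }
    if (!is.null(raw$effects)) raw$effects <- as.matrix(raw$effects)
    if (!is.null(raw$group_sizes)) raw$group_sizes <- unlist(raw$group_sizes)
  }
  do.call(fn, raw[intersect(names(raw), names(formals(fn)))])
}

#' Run the full group-by-visit band-power analysis
#'
#' From recordings (or a precomputed band-power table) to the complete
#' statistical report: per band and zone, the seeded resampling mixed
#' ANOVA; per visit, Kruskal-Wallis across the three arms plus pairwise
#' rank-sum tests with unpaired Cliff's delta; per arm, the between-visit
#' signed-rank test with paired Cliff's delta; plus the pooled Spearman /
#' FDR correlation matrix against the neuropsychological scores and its
#' collapsed view. When per-electrode powers are available, a per-group,
#' per-electrode paired-delta table is added (topographic summary). Zone
#' deltas are computed on zone-averaged powers, not averaged electrode
#' deltas.
#'
#' @param cohort List with `recordings` (named list of annotated
#'   [eeg_recording()]s) or `band_powers` (long zone table), plus
#'   `metadata` and optionally `scores`.
#' @param config An [analysis_config()].
#' @return A list of class `qeeg_results` with tidy data.frames:
#'   `zone_powers`, `electrode_powers` (or NULL), `anova`,
#'   `between_groups`, `within_groups`, `correlations`,
#'   `correlations_collapsed`, `electrode_paired_delta` (or NULL), and
#'   `manifest`.
#' @export
run_analysis <- function(cohort, config = analysis_config()) {
  montage <- montage_32(config$zone_file)
  if (!is.null(cohort$recordings)) {
    pp_args <- if (isTRUE(config$preprocess)) {
      list(target_fs = config$target_fs, notch_hz = config$notch_hz)
    } else NULL
    tabs <- band_power_table(cohort$recordings, montage,
                             preprocess_args = pp_args,
                             window_s = config$window_s,
                             overlap = config$overlap)
    zone_tab <- tabs$zones
    elec_tab <- tabs$electrodes
  } else if (!is.null(cohort$band_powers)) {
    zone_tab <- cohort$band_powers
    elec_tab <- NULL
  } else {
    stop("cohort must contain `recordings` or `band_powers`")
  }

  bands <- unique(zone_tab$band)
  zones <- unique(zone_tab$zone)
  groups <- sort(unique(zone_tab$group))
  anova_rows <- list(); between_rows <- list(); within_rows <- list()
  for (z in zones) {
    for (b in bands) {
      cell <- zone_tab[zone_tab$zone == z & zone_tab$band == b, ]
      av <- resampling_mixed_anova(
        data.frame(subject_id = cell$subject_id, group = cell$group,
                   visit = cell$visit, value = cell$relative_power),
        n_iter = config$n_iter, seed = config$seed)
      anova_rows[[length(anova_rows) + 1L]] <-
        data.frame(zone = z, band = b, p_group = av$p_group,
                   p_visit = av$p_visit,
                   p_interaction = av$p_interaction,
                   marker_group = significance_marker(av$p_group),
                   marker_visit = significance_marker(av$p_visit),
                   marker_interaction =
                     significance_marker(av$p_interaction),
                   n_iter = av$n_iter, seed = av$seed,
                   stringsAsFactors = FALSE)
      for (v in c("V1", "V2")) {
        vis <- cell[cell$visit == v, ]
        samples <- split(vis$relative_power, vis$group)[groups]
        kw <- kruskal_wallis(samples)
        between_rows[[length(between_rows) + 1L]] <-
          data.frame(zone = z, band = b, visit = v, contrast = "omnibus",
                     statistic = kw$statistic, p = kw$p, marker = kw$marker,
                     delta = NA_real_, delta_label = NA_character_,
                     n1 = NA_integer_, n2 = NA_integer_,
                     stringsAsFactors = FALSE)
        pairs <- utils::combn(groups, 2, simplify = FALSE)
        for (pr in pairs) {
          rs <- wilcoxon_rank_sum(samples[[pr[1]]], samples[[pr[2]]])
          es <- cliffs_delta(samples[[pr[1]]], samples[[pr[2]]])
          between_rows[[length(between_rows) + 1L]] <-
            data.frame(zone = z, band = b, visit = v,
                       contrast = paste(pr[1], "vs", pr[2]),
                       statistic = rs$statistic, p = rs$p,
                       marker = rs$marker, delta = es$delta,
                       delta_label = es$label, n1 = es$n_x, n2 = es$n_y,
                       stringsAsFactors = FALSE)
        }
      }
      for (g in groups) {
        sub <- cell[cell$group == g, ]
        wide <- merge(sub[sub$visit == "V1", c("subject_id", "relative_power")],
                      sub[sub$visit == "V2", c("subject_id", "relative_power")],
                      by = "subject_id")
        sr <- wilcoxon_signed_rank(wide$relative_power.x,
                                   wide$relative_power.y)
        es <- paired_cliffs_delta(wide$relative_power.x,
                                  wide$relative_power.y)
        within_rows[[length(within_rows) + 1L]] <-
          data.frame(zone = z, band = b, group = g,
                     statistic = sr$statistic, p = sr$p,
                     marker = sr$marker, delta = es$delta,
                     delta_label = es$label, n = es$n_x,
                     stringsAsFactors = FALSE)
      }
    }
  }

  correlations <- NULL; collapsed <- NULL
  if (!is.null(cohort$scores)) {
    correlations <- spearman_with_fdr(zone_tab, cohort$scores)
    collapsed <- collapse_correlation_matrix(correlations,
                                             config$collapse_threshold)
  }

  elec_delta <- NULL
  if (!is.null(elec_tab)) {
    rows <- list()
    for (g in groups) {
      for (b in bands) {
        sub <- elec_tab[elec_tab$group == g & elec_tab$band == b, ]
        for (ch in unique(sub$channel)) {
          chs <- sub[sub$channel == ch, ]
          wide <- merge(chs[chs$visit == "V1",
                            c("subject_id", "relative_power")],
                        chs[chs$visit == "V2",
                            c("subject_id", "relative_power")],
                        by = "subject_id")
          es <- paired_cliffs_delta(wide$relative_power.x,
                                    wide$relative_power.y)
          rows[[length(rows) + 1L]] <-
            data.frame(group = g, band = b, channel = ch,
                       delta = es$delta, delta_label = es$label,
                       n = es$n_x, stringsAsFactors = FALSE)
        }
      }
    }
    elec_delta <- do.call(rbind, rows)
  }

  manifest <- list(
    package = "qeegr",
    version = as.character(utils::packageVersion("qeegr")),
    config = unclass(config),
    n_subjects = length(unique(zone_tab$subject_id)),
    groups = as.list(table(unique(
      zone_tab[, c("subject_id", "group")])$group)),
    bands = bands, zones = zones)

  structure(list(zone_powers = zone_tab, electrode_powers = elec_tab,
                 anova = do.call(rbind, anova_rows),
                 between_groups = do.call(rbind, between_rows),
                 within_groups = do.call(rbind, within_rows),
                 correlations = correlations,
                 correlations_collapsed = collapsed,
                 electrode_paired_delta = elec_delta,
                 manifest = manifest),
            class = "qeeg_results")
}

#' @export
print.qeeg_results <- function(x, ...) {
  cat("qEEG analysis results:\n")
  cat(sprintf("  %d subjects, %d zones x %d bands\n",
              x$manifest$n_subjects, length(x$manifest$zones),
              length(x$manifest$bands)))
  sig <- x$anova[x$anova$p_visit < 0.05, c("zone", "band", "p_visit")]
  if (nrow(sig) > 0) {
    cat("  visit effects at p < 0.05:\n")
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("    %s %s: p = %.3f\n", sig$zone[i], sig$band[i],
                  sig$p_visit[i]))
    }
  } else cat("  no visit effects at p < 0.05\n")
  invisible(x)
}

#' Write an analysis results bundle to disk
#'
#' Tidy CSV per table plus a JSON run manifest. Output is deterministic
#' given the input bundle (no timestamps), so identical runs produce
#' byte-identical files.
#'
#' @param results A `qeeg_results` bundle from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  tables <- c("zone_powers", "electrode_powers", "anova", "between_groups",
              "within_groups", "correlations", "correlations_collapsed",
              "electrode_paired_delta")
  for (tb in tables) {
    df <- results[[tb]]
    if (is.null(df)) next
    path <- file.path(dir, paste0(tb, ".csv"))
    utils::write.csv(format(df, digits = 12, trim = TRUE), path,
                     row.names = FALSE)
    written <- c(written, path)
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(results$manifest, mpath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(written, mpath))
}
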