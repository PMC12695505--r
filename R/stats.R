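#' Significance marker for a p-value
#'
#' The figure-annotation convention: `***` for p < 0.001, `**` for
#' p < 0.01, `*` for p < 0.05, a bullet (U+2022) for p < 0.1 (trend), `n.s.`
#' otherwise. Thresholds are strict inequalities; the most extreme
#' applicable marker wins.
#'
#' @param p A probability in `[0, 1]`.
#' @return One of `"***"`, `"**"`, `"*"`, `"\u2022"`, `"n.s."`.
#' @examples
#' significance_marker(0.012)  # "*"
#' significance_marker(0.064)  # bullet (trend)
#' @export
significance_marker <- function(p) {
  if (!is.finite(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (p < 0.001) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else if (p < 0.1) "\u2022"
  else "n.s."
}

test_result <- function(method, statistic, p, n) {
  structure(list(method = method, statistic = unname(statistic),
                 p = unname(p), n = n, marker = significance_marker(p)),
            class = "qeeg_test")
}

#' @export
print.qeeg_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g %s (n = %s)\n", x$method,
              x$statistic, x$p, x$marker, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based comparison of two or more independent groups, with tie
#' correction and a chi-square reference on k - 1 degrees of freedom.
#'
#' @param groups List of two or more non-empty numeric samples.
#' @return A test result (method, statistic, p, per-group n, marker).
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0)) {
    stop("all groups must be non-empty")
  }
  kt <- stats::kruskal.test(groups)
  test_result("Kruskal-Wallis", kt$statistic, kt$p.value,
              vapply(groups, length, integer(1)))
}

#' Wilcoxon rank-sum test (two independent samples)
#'
#' Exact two-sided p-value when the combined sample size is at most 25 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y Non-empty numeric samples.
#' @return A test result.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= 25
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1    # complete-tie degeneracy (zero variance)
  test_result("Wilcoxon rank-sum", wt$statistic, min(p, 1),
              c(length(x), length(y)))
}

#' Wilcoxon signed-rank test (paired samples)
#'
#' Zero differences are dropped (classic Wilcoxon convention). The
#' p-value is exact for at most 25 non-zero differences without tied
#' magnitudes (signed-rank distribution), exact by full enumeration of
#' sign patterns with midranks for at most 14 differences when magnitudes
#' tie, and otherwise the corrected normal approximation. If every
#' difference is zero the test is degenerate: p = 1 with a warning.
#'
#' @param x1,x2 Equal-length numeric vectors matched by subject order.
#' @return A test result.
#' @export
wilcoxon_signed_rank <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("paired samples differ in length")
  if (length(x1) == 0) stop("samples must be non-empty")
  d <- x2 - x1
  if (all(d == 0)) {
    warning("all paired differences are zero; test is degenerate")
    return(test_result("Wilcoxon signed-rank", 0, 1, length(x1)))
  }
  dn <- d[d != 0]
  ties <- anyDuplicated(abs(dn)) > 0
  if (ties && length(dn) <= 14) {
    res <- signed_rank_enumerated(dn)
    return(test_result("Wilcoxon signed-rank", res$statistic, res$p,
                       length(x1)))
  }
  exact <- !ties && length(dn) <= 25
  wt <- suppressWarnings(stats::wilcox.test(x2, x1, paired = TRUE,
                                            exact = exact, correct = TRUE))
  test_result("Wilcoxon signed-rank", wt$statistic, wt$p.value, length(x1))
}

# Exact two-sided signed-rank p under ties: enumerate all 2^n sign
# patterns of the midranked magnitudes (n <= 14).
signed_rank_enumerated <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  m <- 2^n
  v_all <- numeric(m)
  for (bit in seq_len(n)) {
    pattern <- rep(rep(c(0, 1), each = 2^(bit - 1)), length.out = m)
    v_all <- v_all + pattern * r[bit]
  }
  list(statistic = v_obs,
       p = mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9))
}

## ---- resampling mixed-design ANOVA ----

#' Resampling mixed-design ANOVA (groups x visits)
#'
#' Omnibus comparison for the split-plot design with one between-subject
#' factor (treatment group, >= 2 levels) and one two-level within-subject
#' factor (visit). For two visits the design decomposes exactly into the
#' per-subject difference `d = V2 - V1` (visit and interaction effects) and
#' the per-subject mean `s = (V1 + V2) / 2` (group effect). Wald-type
#' statistics with heteroscedasticity-robust variance estimates are
#' referenced against a wild-bootstrap null (Rademacher multipliers on
#' group-centred values), giving a fully seeded, distribution-free
#' resampling test. This is a documented stand-in for resampling ANOVA
#' packages: the contract is design fidelity and type-I calibration, not
#' equivalence with any specific implementation.
#'
#' The visit hypothesis is the unweighted mean of per-group visit effects
#' being zero (the factorial main effect); the interaction hypothesis is
#' equality of per-group visit effects; the group hypothesis is equality of
#' per-group subject means.
#'
#' @param data Data.frame with columns `subject_id`, `group`, `visit`
#'   (`"V1"`/`"V2"`), `value`. Subjects missing one visit are dropped with
#'   a warning.
#' @param n_iter Number of resampling iterations (default 10000).
#' @param seed Integer seed (default 20000523); the run is fully
#'   reproducible given `(data, n_iter, seed)` and does not disturb the
#'   caller's RNG state.
#' @return An object of class `anova_result`: `p_group`, `p_visit`,
#'   `p_interaction`, the observed statistics, `n_iter`, `seed`,
#'   `statistic_type`.
#' @export
resampling_mixed_anova <- function(data, n_iter = 10000, seed = 20000523) {
  need <- c("subject_id", "group", "visit", "value")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  wide <- split_to_wide(data)
  groups <- split(wide, wide$group)
  if (length(groups) < 2) stop("need at least 2 groups with complete subjects")
  if (any(vapply(groups, nrow, integer(1)) < 2)) {
    stop("every group needs at least 2 subjects with both visits")
  }
  d_list <- lapply(groups, function(g) g$v2 - g$v1)
  s_list <- lapply(groups, function(g) (g$v1 + g$v2) / 2)

  obs_group <- wald_equal_means(s_list)
  obs_inter <- wald_equal_means(d_list)
  obs_visit <- wald_zero_grand_mean(d_list)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  boot_group <- wild_boot_stats(s_list, n_iter, wald_equal_means_boot)
  boot_inter <- wild_boot_stats(d_list, n_iter, wald_equal_means_boot)
  boot_visit <- wild_boot_stats(d_list, n_iter, wald_zero_grand_mean_boot)

  pval <- function(obs, boot) (1 + sum(boot >= obs)) / (length(boot) + 1)
  structure(list(p_group = pval(obs_group, boot_group),
                 p_visit = pval(obs_visit, boot_visit),
                 p_interaction = pval(obs_inter, boot_inter),
                 statistic_group = obs_group,
                 statistic_visit = obs_visit,
                 statistic_interaction = obs_inter,
                 n_iter = n_iter, seed = seed,
                 n_subjects = vapply(groups, nrow, integer(1)),
                 statistic_type = "Wald-type, wild bootstrap (Rademacher)"),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf(paste0("Resampling mixed ANOVA (%s; %d iterations, seed %d)\n",
                     "  group:       p = %.4g %s\n",
                     "  visit:       p = %.4g %s\n",
                     "  interaction: p = %.4g %s\n"),
              x$statistic_type, x$n_iter, x$seed,
              x$p_group, significance_marker(x$p_group),
              x$p_visit, significance_marker(x$p_visit),
              x$p_interaction, significance_marker(x$p_interaction)))
  invisible(x)
}

split_to_wide <- function(data) {
  v1 <- data[data$visit == "V1", c("subject_id", "group", "value")]
  v2 <- data[data$visit == "V2", c("subject_id", "group", "value")]
  names(v1)[3] <- "v1"; names(v2)[3] <- "v2"
  wide <- merge(v1, v2, by = c("subject_id", "group"))
  lost <- setdiff(unique(data$subject_id), wide$subject_id)
  if (length(lost) > 0) {
    warning("dropping subject(s) without both visits: ",
            paste(lost, collapse = ", "))
  }
  wide[order(wide$group, wide$subject_id), ]
}

# Wald statistic for equality of k group means with heteroscedastic
# variance-of-mean estimates (general k via generalized inverse).
wald_equal_means <- function(x_list) {
  k <- length(x_list)
  m <- vapply(x_list, mean, numeric(1))
  v <- vapply(x_list, function(x) stats::var(x) / length(x), numeric(1))
  cmat <- cbind(1, diag(-1, k - 1))        # m1 - mj, j = 2..k
  cm <- as.vector(cmat %*% m)
  cvc <- cmat %*% diag(v, k) %*% t(cmat)
  as.numeric(t(cm) %*% solve(cvc, cm))
}

# Squared t-type statistic for the unweighted grand mean being zero.
wald_zero_grand_mean <- function(x_list) {
  k <- length(x_list)
  m <- mean(vapply(x_list, mean, numeric(1)))
  v <- sum(vapply(x_list, function(x) stats::var(x) / length(x),
                  numeric(1))) / k^2
  m^2 / v
}

# Vectorized wild bootstrap: for each group, center the values and flip
# signs with Rademacher multipliers; bootstrap means and variances have
# closed forms because squared values are sign-invariant.
wild_boot_moments <- function(x_list, n_iter) {
  lapply(x_list, function(x) {
    xc <- x - mean(x)
    n <- length(x)
    e <- matrix(sample(c(-1, 1), n * n_iter, replace = TRUE), nrow = n)
    mb <- colMeans(xc * e)
    ssq <- sum(xc^2)
    vb <- (ssq - n * mb^2) / ((n - 1) * n)   # var of bootstrap mean
    list(mb = mb, vb = pmax(vb, .Machine$double.eps))
  })
}

wild_boot_stats <- function(x_list, n_iter, stat_fn) {
  mom <- wild_boot_moments(x_list, n_iter)
  stat_fn(mom)
}

wald_equal_means_boot <- function(mom) {
  k <- length(mom)
  n_iter <- length(mom[[1]]$mb)
  mb <- vapply(mom, `[[`, numeric(n_iter), "mb")
  vb <- vapply(mom, `[[`, numeric(n_iter), "vb")
  if (k == 3) {
    # closed-form 2x2 inverse for the 3-group case (the common path)
    a <- mb[, 1] - mb[, 2]; b <- mb[, 1] - mb[, 3]
    v1 <- vb[, 1]; v2 <- vb[, 2]; v3 <- vb[, 3]
    det <- (v1 + v2) * (v1 + v3) - v1^2
    (a^2 * (v1 + v3) - 2 * a * b * v1 + b^2 * (v1 + v2)) / det
  } else {
    vapply(seq_len(n_iter), function(i) {
      wald_from_moments(mb[i, ], vb[i, ])
    }, numeric(1))
  }
}

wald_from_moments <- function(m, v) {
  k <- length(m)
  cmat <- cbind(1, diag(-1, k - 1))
  cm <- as.vector(cmat %*% m)
  cvc <- cmat %*% diag(v, k) %*% t(cmat)
  as.numeric(t(cm) %*% solve(cvc, cm))
}

wald_zero_grand_mean_boot <- function(mom) {
  k <- length(mom)
  n_iter <- length(mom[[1]]$mb)
  mb <- vapply(mom, `[[`, numeric(n_iter), "mb")
  vb <- vapply(mom, `[[`, numeric(n_iter), "vb")
  rowMeans(mb)^2 / (rowSums(vb) / k^2)
}

## ---- Spearman correlations with FDR ----

#' Spearman correlations between band powers and scores, FDR-adjusted
#'
#' Correlates every (zone, band) relative power with every
#' neuropsychological score, pooling subjects across groups and treating
#' each subject-visit as one observation. Missing score cells are handled
#' by pairwise deletion: each cell uses only its complete pairs. Cells
#' with fewer than `min_pairs` complete pairs are flagged unavailable and
#' excluded from the adjustment. Benjamini-Hochberg adjustment is applied
#' across the whole matrix as one family.
#'
#' @param powers Long band-power table (columns `subject_id`, `visit`,
#'   `zone`, `band`, `relative_power`), e.g. `band_power_table()$zones`.
#' @param scores Score table (columns `subject_id`, `visit`, one column
#'   per test; NA allowed).
#' @param min_pairs Minimum complete pairs per cell (default 3).
#' @return Data.frame with one row per (zone, band, score) cell: `rho`,
#'   `p_raw`, `p_adj`, `n_pairs` (NA rho/p for unavailable cells).
#' @export
spearman_with_fdr <- function(powers, scores, min_pairs = 3) {
  key <- interaction(powers$zone, powers$band, sep = ":", drop = TRUE)
  score_cols <- setdiff(names(scores), c("subject_id", "group", "visit"))
  obs_key <- paste(powers$subject_id, powers$visit, sep = "@")
  score_key <- paste(scores$subject_id, scores$visit, sep = "@")
  cells <- list()
  for (pk in levels(key)) {
    sel <- key == pk
    pw <- powers$relative_power[sel]
    idx <- match(obs_key[sel], score_key)
    zone <- powers$zone[sel][1]; band <- powers$band[sel][1]
    for (sc in score_cols) {
      sv <- scores[[sc]][idx]
      ok <- !is.na(sv) & !is.na(pw)
      n_pairs <- sum(ok)
      if (n_pairs < min_pairs) {
        cells[[length(cells) + 1L]] <-
          data.frame(zone = zone, band = band, score = sc,
                     rho = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
                     n_pairs = n_pairs, stringsAsFactors = FALSE)
      } else {
        ct <- suppressWarnings(stats::cor.test(pw[ok], sv[ok],
                                               method = "spearman",
                                               exact = FALSE))
        cells[[length(cells) + 1L]] <-
          data.frame(zone = zone, band = band, score = sc,
                     rho = unname(ct$estimate), p_raw = ct$p.value,
                     p_adj = NA_real_, n_pairs = n_pairs,
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, cells)
  avail <- !is.na(out$p_raw)
  out$p_adj[avail] <- stats::p.adjust(out$p_raw[avail], method = "BH")
  out
}

#' Collapse a correlation matrix to its significant rows and columns
#'
#' Keeps a (zone, band) row and a score column if and only if it contains
#' at least one cell with adjusted p below `threshold`. An empty result is
#' allowed.
#'
#' @param cells Output of [spearman_with_fdr()].
#' @param threshold Adjusted-p threshold (default 0.1).
#' @return The qualifying subset of `cells` (rows restricted to retained
#'   (zone, band) x score combinations).
#' @export
collapse_correlation_matrix <- function(cells, threshold = 0.1) {
  hit <- !is.na(cells$p_adj) & cells$p_adj < threshold
  rows_keep <- unique(cells[hit, c("zone", "band")])
  cols_keep <- unique(cells$score[hit])
  if (nrow(rows_keep) == 0) return(cells[0, ])
  row_key <- paste(cells$zone, cells$band)
  keep <- row_key %in% paste(rows_keep$zone, rows_keep$band) &
    cells$score %in% cols_keep
  cells[keep, ]
}
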