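test_that("significance markers follow the printed convention", {
  expect_identical(significance_marker(0.012), "*")
  expect_identical(significance_marker(0.064), "•")
  expect_identical(significance_marker(0.0005), "***")
  expect_identical(significance_marker(0.005), "**")
  expect_identical(significance_marker(0.2), "n.s.")
  # strict thresholds
  expect_identical(significance_marker(0.05), "•")
  expect_identical(significance_marker(0.1), "n.s.")
  expect_error(significance_marker(1.5), "\\[0, 1\\]")
})

test_that("Kruskal-Wallis separates separated groups and enforces inputs", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(10, 11, 12), c(20, 21, 22)))
  expect_lt(res$p, 0.05)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("Kruskal-Wallis agrees with a permutation oracle on tiny samples", {
  set.seed(201)
  x <- list(rnorm(4), rnorm(4), rnorm(4))
  obs <- kruskal_wallis(x)$statistic
  pooled <- unlist(x)
  sizes <- lengths(x)
  perm_stats <- replicate(4000, {
    p <- sample(pooled)
    kruskal_wallis(split(p, rep(seq_along(sizes), sizes)))$statistic
  })
  p_perm <- mean(perm_stats >= obs - 1e-9)
  p_chisq <- kruskal_wallis(x)$p
  # chi-square approximation tracks the permutation null reasonably at n=4
  expect_equal(p_chisq, p_perm, tolerance = 0.1)
})

test_that("rank-sum exact p matches exhaustive enumeration", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p, 0.1)
  expect_equal(res$p, rank_sum_exact_oracle(c(1, 2, 3), c(4, 5, 6)))
  set.seed(202)
  for (i in 1:25) {
    x <- rnorm(sample(3:6, 1))
    y <- rnorm(sample(3:6, 1))
    expect_equal(wilcoxon_rank_sum(x, y)$p, rank_sum_exact_oracle(x, y),
                 tolerance = 1e-9)
  }
  same <- c(4, 4, 4)
  expect_gte(wilcoxon_rank_sum(same, same)$p, 0.99)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("signed-rank exact p matches exhaustive sign enumeration", {
  # uniform shift: all |d| tied, most extreme table of the 2^6 patterns
  x1 <- c(1.2, 0.4, 2.2, 3.1, 0.9, 1.7)
  res <- wilcoxon_signed_rank(x1, x1 + 1)
  expect_equal(res$p, 2 / 64)
  expect_equal(res$p, signed_rank_exact_oracle(rep(1, 6)))
  set.seed(203)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    a <- rnorm(n); b <- rnorm(n)
    expect_equal(wilcoxon_signed_rank(a, b)$p,
                 signed_rank_exact_oracle(b - a), tolerance = 1e-9)
  }
  # tied magnitudes of mixed sign, against the midrank oracle
  for (i in 1:10) {
    d <- sample(c(-2, -1, 1, 2), 8, replace = TRUE)
    expect_equal(wilcoxon_signed_rank(rep(0, 8), d)$p,
                 signed_rank_exact_oracle(d), tolerance = 1e-9)
  }
  expect_warning(res0 <- wilcoxon_signed_rank(1:4, 1:4), "degenerate")
  expect_equal(res0$p, 1)
  # antisymmetry of the design: swapping visits keeps p
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(wilcoxon_signed_rank(a, b)$p, wilcoxon_signed_rank(b, a)$p)
})

test_that("rank-based tests are invariant to monotone transforms", {
  set.seed(204)
  x <- rexp(12); y <- rexp(15) * 1.5; z <- rexp(9)
  tr <- function(v) log(v + 1)
  expect_equal(wilcoxon_rank_sum(x, y)$p,
               wilcoxon_rank_sum(tr(x), tr(y))$p)
  expect_equal(kruskal_wallis(list(x, y, z))$p,
               kruskal_wallis(list(tr(x), tr(y), tr(z)))$p)
  expect_equal(cliffs_delta(x, y)$delta, cliffs_delta(tr(x), tr(y))$delta)
  # paired delta depends only on signs of change, so it shares the
  # invariance; the signed-rank statistic itself does not (|d| ranks move)
  a <- rnorm(10); b <- a + rnorm(10)
  expect_equal(paired_cliffs_delta(exp(a), exp(b))$delta,
               paired_cliffs_delta(a, b)$delta)
})

test_that("resampling ANOVA is deterministic and validates its design", {
  set.seed(205)
  d <- data.frame(
    subject_id = rep(sprintf("s%02d", 1:12), each = 2),
    group = rep(rep(c("A", "B", "C"), each = 4), each = 2),
    visit = rep(c("V1", "V2"), 12),
    value = rnorm(24))
  a1 <- resampling_mixed_anova(d, n_iter = 500, seed = 99)
  a2 <- resampling_mixed_anova(d, n_iter = 500, seed = 99)
  expect_identical(unclass(a1), unclass(a2))
  a3 <- resampling_mixed_anova(d, n_iter = 2000, seed = 100)
  expect_lt(abs(a3$p_visit - a1$p_visit), 0.1)
  # incomplete subject dropped with warning
  expect_warning(resampling_mixed_anova(d[-1, ], n_iter = 50, seed = 1),
                 "s01")
  # group with < 2 complete subjects errors
  bad <- d[d$group != "A" | d$subject_id == "s01", ]
  expect_error(resampling_mixed_anova(bad, n_iter = 50, seed = 1),
               "at least 2 subjects")
  # caller RNG state is untouched
  set.seed(42); before <- rnorm(1)
  set.seed(42); invisible(resampling_mixed_anova(d, n_iter = 50, seed = 7))
  expect_identical(rnorm(1), before)
})

test_that("resampling ANOVA detects a pure visit effect", {
  set.seed(206)
  n <- 15
  subj <- sprintf("s%02d", 1:(3 * n))
  grp <- rep(c("A", "B", "C"), each = n)
  v1 <- rnorm(3 * n)
  v2 <- v1 + 0.8 + rnorm(3 * n, sd = 0.5)
  d <- data.frame(subject_id = rep(subj, 2),
                  group = rep(grp, 2),
                  visit = rep(c("V1", "V2"), each = 3 * n),
                  value = c(v1, v2))
  a <- resampling_mixed_anova(d, n_iter = 2000, seed = 3)
  expect_lt(a$p_visit, 0.01)
  expect_gt(a$p_group, 0.05)
})

test_that("BH adjustment reproduces hand-checked cases and its invariants", {
  powers <- data.frame(subject_id = rep(sprintf("s%d", 1:20), 2),
                       visit = rep(c("V1", "V2"), each = 20),
                       zone = "whole_scalp", band = "alpha",
                       relative_power = NA_real_)
  # hand case via p.adjust contract on the module's own output is covered
  # in the pipeline tests; here the arithmetic cases:
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(207)
  p <- runif(30)
  adj <- stats::p.adjust(p, "BH")
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("spearman_with_fdr handles pooling, deletion and flagging", {
  set.seed(208)
  n <- 25
  subj <- sprintf("s%02d", 1:n)
  powers <- do.call(rbind, lapply(c("V1", "V2"), function(v) {
    do.call(rbind, lapply(c("alpha", "delta"), function(b) {
      data.frame(subject_id = subj, group = "CRB_sham", visit = v,
                 zone = "whole_scalp", band = b,
                 relative_power = runif(n))
    }))
  }))
  alpha_vals <- powers$relative_power[powers$band == "alpha"]
  scores <- data.frame(subject_id = rep(subj, 2),
                       visit = rep(c("V1", "V2"), each = n))
  scores$MoCA <- alpha_vals + rnorm(2 * n, sd = 1e-6)  # monotone link
  scores$TMT <- rnorm(2 * n)
  scores$TMT[1:(2 * n - 2)] <- NA                      # only 2 pairs left
  cells <- spearman_with_fdr(powers, scores)
  moca_alpha <- cells[cells$band == "alpha" & cells$score == "MoCA", ]
  expect_equal(moca_alpha$rho, 1, tolerance = 1e-9)
  expect_equal(moca_alpha$n_pairs, 2 * n)
  expect_true(all(is.na(cells$p_adj[cells$score == "TMT"])))
  expect_equal(unique(cells$n_pairs[cells$score == "TMT"]), 2)
  ok <- !is.na(cells$p_raw)
  expect_true(all(cells$p_adj[ok] >= cells$p_raw[ok] - 1e-12))
})

test_that("null correlations reject at the nominal rate", {
  set.seed(209)
  hits <- 0
  reps <- 1000
  for (i in seq_len(reps)) {
    p <- suppressWarnings(stats::cor.test(rnorm(25), rnorm(25),
                                          method = "spearman",
                                          exact = FALSE)$p.value)
    hits <- hits + (p < 0.05)
  }
  expect_gt(hits / reps, 0.03)
  expect_lt(hits / reps, 0.07)
})

test_that("correlation-matrix collapse keeps exactly the qualifying rows", {
  cells <- expand.grid(zone = c("frontal", "central"),
                       band = c("alpha", "delta"),
                       score = c("MoCA", "TMT", "PSI"),
                       stringsAsFactors = FALSE)
  cells$rho <- 0.1
  cells$p_raw <- 0.5
  cells$p_adj <- 0.5
  cells$n_pairs <- 40
  expect_equal(nrow(collapse_correlation_matrix(cells)), 0)
  cells$p_adj[cells$zone == "central" & cells$band == "alpha" &
                cells$score == "MoCA"] <- 0.01
  kept <- collapse_correlation_matrix(cells)
  expect_setequal(unique(kept$score), "MoCA")
  expect_equal(nrow(kept), 1)
  # random matrices: every retained row/column has a qualifying cell
  set.seed(210)
  for (i in 1:10) {
    cells$p_adj <- runif(nrow(cells), 0, 0.3)
    kept <- collapse_correlation_matrix(cells)
    if (nrow(kept) == 0) next
    for (z in unique(paste(kept$zone, kept$band))) {
      expect_true(any(kept$p_adj[paste(kept$zone, kept$band) == z] < 0.1))
    }
    for (sc in unique(kept$score)) {
      expect_true(any(kept$p_adj[kept$score == sc] < 0.1))
    }
  }
})
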