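#' Two-sample two-sided Kolmogorov-Smirnov comparison
#'
#' Compares the pooled per-component distributions of one metric (raw
#' values or Z-scores) between two groups. The exact p-value is used
#' when both samples have at most 25 observations, the asymptotic
#' approximation above that.
#'
#' @param x,y Numeric samples (NAs dropped).
#' @param metric Name carried into the result.
#' @return One-row data.frame: `metric`, `statistic` (D), `p_raw`,
#'   `n1`, `n2`.
#' @export
ks_compare <- function(x, y, metric = NA_character_) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop_invalid("both samples must be non-empty")
  exact <- length(x) <= 25 && length(y) <= 25
  kt <- suppressWarnings(ks.test(x, y, alternative = "two.sided",
                                 exact = exact))
  data.frame(metric = metric, statistic = unname(kt$statistic),
             p_raw = min(1, kt$p.value), n1 = length(x), n2 = length(y))
}

#' Sidak-corrected significance threshold
#'
#' Per-test threshold `1 - (1 - alpha)^(1/m)` controlling the
#' family-wise error at `alpha` over `m` tests.
#'
#' @param alpha Family-wise level.
#' @param m Number of tests in the family, at least 1 (vectorized).
#' @return The per-test threshold(s).
#' @export
sidak_threshold <- function(alpha = 0.05, m) {
  if (any(m < 1)) stop_invalid("family size m must be >= 1")
  1 - (1 - alpha)^(1 / m)
}

#' Flag a family of tests by the Sidak rule
#'
#' @param tests data.frame with a `p_raw` column (one family, e.g. all
#'   metrics of one group comparison).
#' @param alpha Family-wise level.
#' @return The input with `sidak_threshold` and logical
#'   `p_significant_after_sidak` columns appended.
#' @export
apply_sidak <- function(tests, alpha = 0.05) {
  thr <- sidak_threshold(alpha, nrow(tests))
  tests$sidak_threshold <- thr
  tests$p_significant_after_sidak <- tests$p_raw <= thr
  tests
}

#' KS test family over a metric panel
#'
#' Runs [ks_compare()] for every metric column present in both group
#' tables and applies the Sidak correction with the panel as the family.
#'
#' @param tbl_a,tbl_b [metrics_table()]-style data.frames for the two
#'   groups.
#' @param metrics Character vector of metric columns.
#' @param size_filter Optional inclusive `c(min, max)` size filter
#'   applied to both tables before pooling.
#' @param alpha Family-wise level.
#' @return data.frame, one row per metric, Sidak-flagged.
#' @export
ks_test_family <- function(tbl_a, tbl_b, metrics, size_filter = NULL,
                           alpha = 0.05) {
  rows <- lapply(metrics, function(mm) {
    ks_compare(global_metric_distribution(tbl_a, mm, size_filter),
               global_metric_distribution(tbl_b, mm, size_filter),
               metric = mm)
  })
  apply_sidak(do.call(rbind, rows), alpha)
}

#' Correlate a per-subject network feature with a clinical score
#'
#' Aggregates a metric to one value per subject (mean over that
#' subject's components of the configured size), drops subjects lacking
#' such components or a score, and computes the Pearson correlation with
#' a two-sided p-value from the t-distribution.
#'
#' @param tbl [metrics_table()]- or Z-score-style data.frame with
#'   `subject_id`, `size` and the metric column.
#' @param scores Named numeric vector of clinical scores (names =
#'   subject ids), e.g. UPDRS.
#' @param metric Metric column to aggregate.
#' @param size Component size at which the metric is read (default 28).
#' @return List: `r`, `p`, `n`, `per_subject` (data.frame).
#' @export
correlate_clinical <- function(tbl, scores, metric, size = 28) {
  sub <- tbl[tbl$size == size & !is.na(tbl[[metric]]), ]
  agg <- tapply(sub[[metric]], sub$subject_id, mean)
  ids <- intersect(names(agg), names(scores)[!is.na(scores)])
  if (length(ids) < 3)
    stop_invalid("need >= 3 subjects with both a score and a size-%d component", size)
  x <- unname(agg[ids]); y <- unname(scores[ids])
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(ids),
       per_subject = data.frame(subject_id = ids, value = x, score = y))
}

#' Stability of group metric means under subsampling
#'
#' Robustness report for imbalanced groups: repeatedly draws a random
#' subset of the larger group's subjects (matching the smaller group's
#' size) and recomputes the pooled mean of each metric.
#'
#' @param tbl Metric table of the larger group.
#' @param metrics Metric columns to track.
#' @param n_subjects Subjects per draw.
#' @param n_draws Number of random subsamples.
#' @param seed Seed for the draws.
#' @return data.frame: one row per draw x metric, columns `draw`,
#'   `metric`, `mean`.
#' @export
subsample_stability <- function(tbl, metrics, n_subjects, n_draws = 100,
                                seed = 1L) {
  ids <- unique(tbl$subject_id)
  if (n_subjects > length(ids))
    stop_invalid("n_subjects exceeds available subjects")
  local_seed(seed, {
    rows <- list()
    for (d in seq_len(n_draws)) {
      pick <- sample(ids, n_subjects)
      sub <- tbl[tbl$subject_id %in% pick, ]
      for (mm in metrics) {
        rows[[length(rows) + 1L]] <- data.frame(
          draw = d, metric = mm, mean = mean(sub[[mm]], na.rm = TRUE))
      }
    }
    do.call(rbind, rows)
  })
}
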