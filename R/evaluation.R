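#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a randomly chosen positive
#' outscores a randomly chosen negative, with ties counted 1/2
#' (equivalent to the normalized Mann-Whitney U statistic). Invariant
#' under strictly monotone transforms of the scores.
#'
#' @param scores numeric score vector.
#' @param labels binary labels (0/1, logical, or "mutant"/"wild-type").
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)) # 0.75
roc_auc <- function(scores, labels) {
  y <- normalize_labels(labels)
  stopifnot(length(scores) == length(y))
  n1 <- as.double(sum(y == 1L)); n0 <- as.double(sum(y == 0L))
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties at 1/2
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

normalize_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    stopifnot(all(labels %in% c("mutant", "wild-type")))
    as.integer(labels == "mutant")
  } else as.integer(labels)
}

#' Percentile bootstrap confidence interval for a cohort statistic
#'
#' Resamples the cohort rows with replacement `n_boot` times and reports
#' the percentile 95% interval of the statistic. Resamples on which the
#' statistic is undefined (returns NA, e.g. a resample lacking one
#' class) are redrawn and counted; if undefined draws exceed the number
#' of requested resamples the statistic is deemed undefined on the
#' cohort and an error is raised.
#'
#' @param statistic function taking a cohort data.frame and returning a
#'   single number (NA when undefined on that resample).
#' @param cohort data.frame of samples.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param conf confidence level.
#' @param name statistic name echoed in the estimate.
#' @return An object of class `metric_estimate`: list with `name`,
#'   `point`, `ci_low`, `ci_high`, `n_boot`, `seed`, `n_redrawn`.
#' @export
bootstrap_ci <- function(statistic, cohort, n_boot = 1000L, seed = 1L,
                         conf = 0.95, name = "statistic") {
  stopifnot(nrow(cohort) > 0, n_boot >= 1)
  point <- statistic(cohort)
  vals <- numeric(n_boot)
  n_redrawn <- 0L
  with_seed(split_seed(seed, "bootstrap"), {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(nrow(cohort), replace = TRUE)
        v <- statistic(cohort[idx, , drop = FALSE])
        if (!is.na(v)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > n_boot)
          stop("statistic undefined on more than half of the resamples")
      }
      vals[b] <- v
    }
  })
  a <- (1 - conf) / 2
  ci <- quantile(vals, c(a, 1 - a), names = FALSE, type = 7)
  structure(list(name = name, point = point, ci_low = ci[1], ci_high = ci[2],
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 n_redrawn = n_redrawn),
            class = "metric_estimate")
}

#' Per-subgroup AUC estimates
#'
#' Computes the AUC within each level of `group_field`. For
#' `group_field = "variant"` the default comparator is one-vs-all-
#' negatives: each variant's mutant samples are scored against the full
#' wild-type pool (`variant_mode = "one_vs_all_negatives"`); the
#' alternative `"within"` restricts negatives to the subgroup. Groups
#' where only one class is present are flagged and not computed.
#'
#' @param cohort cohort data.frame with `score`, `ngs_label` and the
#'   grouping column.
#' @param group_field name of the grouping column.
#' @param variant_mode comparator for variant subgroups.
#' @param n_boot bootstrap resamples for the CI (0 to skip CIs).
#' @param seed integer seed.
#' @return data.frame with group, n, auc, ci_low, ci_high, flag.
#' @export
subgroup_metrics <- function(cohort, group_field,
                             variant_mode = c("one_vs_all_negatives", "within"),
                             n_boot = 0L, seed = 1L) {
  variant_mode <- match.arg(variant_mode)
  stopifnot(group_field %in% names(cohort))
  groups <- setdiff(unique(cohort[[group_field]]), "none")
  if (length(groups) == 0L) stop("no groups after filtering")
  res <- lapply(groups, function(g) {
    if (group_field == "variant" && variant_mode == "one_vs_all_negatives") {
      sub <- cohort[cohort[[group_field]] == g & cohort$ngs_label == "mutant" |
                      cohort$ngs_label == "wild-type", , drop = FALSE]
    } else {
      sub <- cohort[cohort[[group_field]] == g, , drop = FALSE]
    }
    y <- normalize_labels(sub$ngs_label)
    if (length(unique(y)) < 2L) {
      return(data.frame(group = g, n = nrow(sub), auc = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        flag = "single_class"))
    }
    if (n_boot > 0L) {
      est <- bootstrap_ci(function(d) {
        yy <- normalize_labels(d$ngs_label)
        if (length(unique(yy)) < 2L) return(NA_real_)
        roc_auc(d$score, yy)
      }, sub, n_boot = n_boot, seed = split_seed(seed, g), name = g)
      data.frame(group = g, n = nrow(sub), auc = est$point,
                 ci_low = est$ci_low, ci_high = est$ci_high, flag = "")
    } else {
      data.frame(group = g, n = nrow(sub), auc = roc_auc(sub$score, y),
                 ci_low = NA_real_, ci_high = NA_real_, flag = "")
    }
  })
  do.call(rbind, res)
}

#' Pearson correlation between paired score vectors
#'
#' Used for cross-scanner concordance of per-slide model scores.
#'
#' @param scores_a,scores_b equal-length numeric vectors (length >= 3).
#' @return Pearson product-moment correlation coefficient.
#' @export
paired_score_correlation <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b) || length(scores_a) < 3L)
    stop("need equal-length vectors with at least 3 pairs")
  if (!all(is.finite(scores_a)) || !all(is.finite(scores_b)))
    stop("scores must be finite")
  if (sd(scores_a) == 0 || sd(scores_b) == 0)
    stop("zero variance in a score vector")
  cor(scores_a, scores_b, method = "pearson")
}

#' Compare score distributions across groups
#'
#' Omnibus Kruskal-Wallis rank test across the levels of `group_field`,
#' followed by pairwise Mann-Whitney (Wilcoxon rank-sum) comparisons.
#' No multiplicity correction is applied by default;
#' `p_adjust = "BH"` enables Benjamini-Hochberg.
#'
#' @param cohort cohort data.frame with `score` and the grouping column.
#' @param group_field name of the grouping column.
#' @param p_adjust p-value adjustment method for the pairwise tests.
#' @return List with `omnibus` (statistic, p, df) and `pairwise`
#'   data.frame (group1, group2, statistic, p, n1, n2).
#' @export
score_distribution_test <- function(cohort, group_field, p_adjust = "none") {
  stopifnot(group_field %in% names(cohort))
  g <- as.factor(cohort[[group_field]])
  if (nlevels(droplevels(g)) < 2L) stop("need at least two groups")
  if (any(table(g) == 0L)) g <- droplevels(g)
  kw <- kruskal.test(cohort$score, g)
  levs <- levels(g)
  pairs <- utils::combn(levs, 2)
  pw <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- cohort$score[g == pairs[1, i]]
    b <- cohort$score[g == pairs[2, i]]
    if (length(a) == 0L || length(b) == 0L) stop("empty group")
    wt <- suppressWarnings(wilcox.test(a, b))
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               statistic = unname(wt$statistic), p = wt$p.value,
               n1 = length(a), n2 = length(b))
  })
  pw <- do.call(rbind, pw)
  pw$p_adj <- p.adjust(pw$p, method = p_adjust)
  list(omnibus = list(statistic = unname(kw$statistic),
                      p = kw$p.value, df = unname(kw$parameter)),
       pairwise = pw)
}

#' Median turnaround time per test
#'
#' Summarizes turnaround records (hours from molecular accession to
#' result availability) into a per-test median and count.
#'
#' @param records data.frame with `sample_id`, `test_name` and `delta_t`
#'   (hours, non-negative).
#' @return data.frame with test_name, median_hours, n.
#' @export
tat_summary <- function(records) {
  stopifnot(all(c("sample_id", "test_name", "delta_t") %in% names(records)),
            nrow(records) >= 1)
  if (any(records$delta_t < 0))
    stop("negative turnaround time: result precedes accession (clock skew?)")
  agg <- aggregate(delta_t ~ test_name, data = records,
                   FUN = function(x) c(median = median(x), n = length(x)))
  data.frame(test_name = agg$test_name,
             median_hours = agg$delta_t[, "median"],
             n = as.integer(agg$delta_t[, "n"]))
}
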