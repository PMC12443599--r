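#' A dual-threshold operating point
#'
#' `t_neg` is the NPV threshold (scores strictly below it are called
#' negative without a rapid test) and `t_pos` the PPV threshold (scores
#' strictly above it are called positive without a rapid test); scores
#' in between fall to the rapid test for confirmation. Scores exactly at
#' either threshold go to the rapid-test branch (conservative boundary).
#'
#' @param t_neg NPV threshold in `[0, 1]`.
#' @param t_pos PPV threshold in `[t_neg, 1]`.
#' @return An object of class `threshold_pair`.
#' @export
threshold_pair <- function(t_neg, t_pos) {
  stopifnot(is.numeric(t_neg), is.numeric(t_pos))
  if (!(t_neg >= 0 && t_neg <= t_pos && t_pos <= 1))
    stop("thresholds must satisfy 0 <= t_neg <= t_pos <= 1")
  structure(list(t_neg = t_neg, t_pos = t_pos), class = "threshold_pair")
}

#' Historical rapid-test benchmark operating characteristics
#'
#' Benchmark performance of the cartridge PCR rapid test against the NGS
#' ground truth: sensitivity 0.918, specificity 0.993, PPV 0.988,
#' NPV 0.954. Used as the noninferiority reference for the assisted
#' workflow and as simulator defaults.
#'
#' @param sensitivity,specificity,ppv,npv benchmark fractions.
#' @param source free-text label of the benchmark's origin.
#' @return An object of class `benchmark_performance`.
#' @export
idylla_benchmark <- function(sensitivity = 0.918, specificity = 0.993,
                             ppv = 0.988, npv = 0.954,
                             source = "historical rapid-test benchmark") {
  vals <- c(sensitivity, specificity, ppv, npv)
  stopifnot(all(vals >= 0), all(vals <= 1))
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 ppv = ppv, npv = npv, source = source),
            class = "benchmark_performance")
}

#' Benchmark implied by rapid-test parameters at a given prevalence
#'
#' The four printed benchmark fractions are rounded and therefore not
#' exactly mutually consistent: no (sensitivity, specificity,
#' prevalence) triplet reproduces all of them simultaneously. For
#' closed-loop simulation studies the self-consistent benchmark is the
#' one the simulated world actually exhibits: sensitivity and
#' specificity as configured, with PPV and NPV derived analytically at
#' the stated prevalence via Bayes' rule.
#'
#' @param sensitivity,specificity rapid-test operating characteristics.
#' @param prevalence mutation prevalence in (0, 1).
#' @param source free-text label.
#' @return A `benchmark_performance` object with implied `ppv`, `npv`.
#' @export
benchmark_from_params <- function(sensitivity = 0.918, specificity = 0.993,
                                  prevalence = implied_prevalence(idylla_benchmark()),
                                  source = "implied by simulator parameters") {
  stopifnot(prevalence > 0, prevalence < 1)
  p <- prevalence
  ppv <- sensitivity * p / (sensitivity * p + (1 - specificity) * (1 - p))
  npv <- specificity * (1 - p) /
    ((1 - sensitivity) * p + specificity * (1 - p))
  idylla_benchmark(sensitivity, specificity, ppv, npv, source = source)
}

#' Screen one sample through the AI-assisted three-branch rule
#'
#' (1) score strictly below `t_neg`: negative, no rapid test; (2) score
#' strictly above `t_pos`: positive, no rapid test; (3) otherwise the
#' rapid-test call is passed through and `rapid_used` is TRUE.
#'
#' @param score model score in `[0, 1]`.
#' @param thresholds a [threshold_pair()].
#' @param rapid_call "positive"/"negative"; required on branch (3).
#' @return List with `call` ("positive"/"negative") and `rapid_used`.
#' @export
screen_sample <- function(score, thresholds, rapid_call = NULL) {
  stopifnot(inherits(thresholds, "threshold_pair"),
            score >= 0, score <= 1)
  if (score < thresholds$t_neg) {
    list(call = "negative", rapid_used = FALSE)
  } else if (score > thresholds$t_pos) {
    list(call = "positive", rapid_used = FALSE)
  } else {
    if (is.null(rapid_call) || is.na(rapid_call) ||
        rapid_call == "not_performed")
      stop("rapid test result required for a mid-zone score")
    stopifnot(rapid_call %in% c("positive", "negative"))
    list(call = rapid_call, rapid_used = TRUE)
  }
}

# Vectorized screening over a cohort; errors if any mid-zone sample
# lacks a rapid call (clinical-safety bias: never silently drop).
screen_cohort <- function(cohort, thresholds) {
  s <- cohort$score
  ai_neg <- s < thresholds$t_neg
  ai_pos <- s > thresholds$t_pos
  mid <- !ai_neg & !ai_pos
  rc <- cohort$rapid_call
  if (any(mid & (is.na(rc) | rc == "not_performed")))
    stop("rapid test result missing for ", sum(mid & (is.na(rc) | rc == "not_performed")),
         " mid-zone sample(s)")
  call <- ifelse(ai_neg, "negative", ifelse(ai_pos, "positive", rc))
  list(call = call, rapid_used = mid)
}

#' Assisted-workflow NPV, PPV and rapid-test reduction on a cohort
#'
#' Screens every sample with the three-branch rule and computes: NPV,
#' the fraction of screen-negatives that are NGS wild-type; PPV, the
#' fraction of screen-positives that are NGS mutant; and test reduction,
#' the fraction of samples for which the rapid test was skipped. A
#' metric with an empty denominator is reported as NA and flagged.
#'
#' @param cohort cohort data.frame with `score`, `ngs_label`,
#'   `rapid_call`.
#' @param thresholds a [threshold_pair()].
#' @return List with `npv`, `ppv`, `test_reduction`, `n_screen_neg`,
#'   `n_screen_pos` and `flags`.
#' @export
assisted_metrics <- function(cohort, thresholds) {
  stopifnot(nrow(cohort) > 0)
  sc <- screen_cohort(cohort, thresholds)
  y <- normalize_labels(cohort$ngs_label)
  neg <- sc$call == "negative"; pos <- sc$call == "positive"
  n_neg <- sum(neg); n_pos <- sum(pos)
  npv <- if (n_neg > 0) sum(neg & y == 0L) / n_neg else NA_real_
  ppv <- if (n_pos > 0) sum(pos & y == 1L) / n_pos else NA_real_
  flags <- character(0)
  if (n_neg == 0) flags <- c(flags, "npv_undefined")
  if (n_pos == 0) flags <- c(flags, "ppv_undefined")
  list(npv = npv, ppv = ppv,
       test_reduction = mean(!sc$rapid_used),
       n_screen_neg = n_neg, n_screen_pos = n_pos, flags = flags)
}

#' Evaluate assisted metrics over a threshold grid
#'
#' Computes assisted NPV, PPV and test reduction at every cell of the
#' `t_neg` x `t_pos` grid. At the (0, 1) corner the workflow reduces no
#' tests and equals the rapid test alone; at (0.5, 0.5) it replaces the
#' rapid test entirely. Reduction is non-decreasing as `t_neg` rises or
#' `t_pos` falls (skipped-set inclusion). Implemented by category-wise
#' threshold counting, exactly equal to calling [assisted_metrics()]
#' per cell.
#'
#' @param cohort cohort data.frame (rapid calls required for all
#'   samples, since every mid-zone is visited across the grid).
#' @param t_neg_range range of NPV thresholds, within `[0, 0.5]`.
#' @param t_pos_range range of PPV thresholds, within `[0.5, 1]`.
#' @param step grid step (default 0.001).
#' @return An object of class `triage_surfaces`: `t_neg`, `t_pos`
#'   vectors and matrices `npv`, `ppv`, `reduction`, `n_neg`, `n_pos`
#'   (rows index `t_neg`, columns `t_pos`).
#' @export
grid_evaluate <- function(cohort, t_neg_range = c(0, 0.5),
                          t_pos_range = c(0.5, 1), step = 0.001) {
  stopifnot(nrow(cohort) > 0, step > 0)
  if (t_neg_range[1] < 0 || t_neg_range[2] > 0.5 ||
      t_pos_range[1] < 0.5 || t_pos_range[2] > 1)
    stop("threshold ranges must lie within [0, 0.5] and [0.5, 1]")
  tn <- seq(t_neg_range[1], t_neg_range[2], by = step)
  tp <- seq(t_pos_range[1], t_pos_range[2], by = step)
  if (length(tn) == 0L || length(tp) == 0L) stop("empty threshold grid")
  rc <- cohort$rapid_call
  if (any(is.na(rc) | rc == "not_performed"))
    stop("rapid test results are required for every sample on the grid")
  y <- normalize_labels(cohort$ngs_label)
  r <- as.integer(rc == "positive")
  n <- nrow(cohort)

  # per (label, rapid) category: counts strictly below each t_neg and
  # strictly above each t_pos
  cats <- list(y0r0 = y == 0L & r == 0L, y0r1 = y == 0L & r == 1L,
               y1r0 = y == 1L & r == 0L, y1r1 = y == 1L & r == 1L)
  below <- lapply(cats, function(sel) {
    s <- sort(cohort$score[sel])
    findInterval(tn, s, left.open = TRUE)  # strict: score < t
  })
  above <- lapply(cats, function(sel) {
    s <- sort(cohort$score[sel])
    length(s) - findInterval(tp, s)        # strict: score > t
  })
  tot <- vapply(cats, sum, integer(1))
  mid <- function(cat) {  # length(tn) x length(tp) matrix of mid-zone counts
    outer(below[[cat]], above[[cat]], function(b, a) tot[[cat]] - b - a)
  }
  M <- lapply(names(cats), mid); names(M) <- names(cats)
  B <- function(cat) matrix(below[[cat]], length(tn), length(tp))
  A <- function(cat) matrix(above[[cat]], length(tn), length(tp), byrow = TRUE)

  n_scr_neg_y0 <- B("y0r0") + B("y0r1") + M$y0r0
  n_scr_neg_y1 <- B("y1r0") + B("y1r1") + M$y1r0
  n_scr_pos_y1 <- A("y1r0") + A("y1r1") + M$y1r1
  n_scr_pos_y0 <- A("y0r0") + A("y0r1") + M$y0r1
  n_neg_m <- n_scr_neg_y0 + n_scr_neg_y1
  n_pos_m <- n_scr_pos_y0 + n_scr_pos_y1
  npv <- ifelse(n_neg_m > 0, n_scr_neg_y0 / n_neg_m, NA_real_)
  ppv <- ifelse(n_pos_m > 0, n_scr_pos_y1 / n_pos_m, NA_real_)
  skipped <- B("y0r0") + B("y0r1") + B("y1r0") + B("y1r1") +
    A("y0r0") + A("y0r1") + A("y1r0") + A("y1r1")
  structure(list(t_neg = tn, t_pos = tp, npv = npv, ppv = ppv,
                 reduction = skipped / n, n_neg = n_neg_m, n_pos = n_pos_m,
                 n = n),
            class = "triage_surfaces")
}

#' Noninferiority region against the benchmark
#'
#' Marks the grid cells whose assisted NPV and PPV are both at least the
#' benchmark value minus `margin`. With `mode = "ci_lower"` the
#' comparison is against supplied lower confidence bounds of the
#' benchmark instead of its point estimates. Cells with an undefined
#' metric are excluded.
#'
#' @param surfaces a [grid_evaluate()] result.
#' @param benchmark an [idylla_benchmark()] object.
#' @param margin noninferiority margin (>= 0; default 0).
#' @param mode "point" or "ci_lower".
#' @param benchmark_ci list with `npv_low`, `ppv_low` for "ci_lower".
#' @return Logical matrix aligned with the surfaces.
#' @export
noninferiority_region <- function(surfaces, benchmark, margin = 0,
                                  mode = c("point", "ci_lower"),
                                  benchmark_ci = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(surfaces, "triage_surfaces"),
            inherits(benchmark, "benchmark_performance"), margin >= 0)
  if (mode == "point") {
    ref_npv <- benchmark$npv; ref_ppv <- benchmark$ppv
  } else {
    stopifnot(!is.null(benchmark_ci))
    ref_npv <- benchmark_ci$npv_low; ref_ppv <- benchmark_ci$ppv_low
  }
  reg <- surfaces$npv >= ref_npv - margin & surfaces$ppv >= ref_ppv - margin
  reg[is.na(reg)] <- FALSE
  reg
}

#' Select operating points of increasing test reduction
#'
#' Returns `k` feasible threshold pairs with strictly increasing rapid-
#' test reduction. The reduction levels are the `i/k` quantiles of
#' the distinct reduction values achieved inside the noninferiority
#' region (so the top level is the maximum feasible reduction; collisions
#' step to the next distinct value);
#' at each level the cell maximizing `min(NPV - benchmark$npv,
#' PPV - benchmark$ppv)` is chosen, ties broken by (t_neg, t_pos)
#' lexicographic order.
#'
#' @param surfaces a [grid_evaluate()] result.
#' @param region logical matrix from [noninferiority_region()].
#' @param benchmark an [idylla_benchmark()] object.
#' @param k number of operating points.
#' @return List of [threshold_pair()]s with `reduction`, `npv`, `ppv`
#'   attached.
#' @export
select_operating_points <- function(surfaces, region, benchmark, k = 3L) {
  stopifnot(inherits(surfaces, "triage_surfaces"), is.matrix(region))
  feas <- which(region)
  if (length(feas) == 0L) stop("no noninferior operating point")
  red <- surfaces$reduction[feas]
  lev <- sort(unique(red))
  if (length(lev) < k)
    stop("cannot find ", k, " strictly increasing reduction levels")
  targets <- unique(quantile(lev, probs = seq_len(k) / k, type = 1,
                             names = FALSE))
  if (length(targets) < k) {  # quantile collisions: take next distinct levels
    extra <- setdiff(lev, targets)
    targets <- c(targets, extra[seq_len(k - length(targets))])
  }
  targets <- sort(targets)[seq_len(k)]
  lapply(targets, function(tv) {
    cells <- feas[red == tv]
    slack <- pmin(surfaces$npv[cells] - benchmark$npv,
                  surfaces$ppv[cells] - benchmark$ppv)
    best <- cells[slack == max(slack)]
    ri <- (best - 1L) %% nrow(region) + 1L
    ci <- (best - 1L) %/% nrow(region) + 1L
    ord <- order(surfaces$t_neg[ri], surfaces$t_pos[ci])
    pick <- ord[1]
    tpair <- threshold_pair(surfaces$t_neg[ri[pick]], surfaces$t_pos[ci[pick]])
    tpair$reduction <- tv
    tpair$npv <- surfaces$npv[best[pick]]
    tpair$ppv <- surfaces$ppv[best[pick]]
    tpair
  })
}

#' Evaluate deployment of selected thresholds on a cohort
#'
#' Computes assisted NPV/PPV/test-reduction point estimates with
#' percentile bootstrap 95% CIs (1,000 resamples by default) for each
#' threshold pair. To guard against leakage the cohort label is checked
#' against the label of the cohort used for threshold selection; a
#' match emits a warning only.
#'
#' @param cohort cohort data.frame.
#' @param thresholds_list list of [threshold_pair()]s.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @param cohort_label label of this cohort.
#' @param selection_label label of the cohort thresholds were chosen on.
#' @return List of operating-point reports (class
#'   `operating_point_report`): threshold pair plus `npv`, `ppv`,
#'   `reduction` [metric_estimate]s.
#' @export
evaluate_deployment <- function(cohort, thresholds_list, n_boot = 1000L,
                                seed = 1L, cohort_label = "deployment",
                                selection_label = NULL) {
  if (!is.null(selection_label) && identical(cohort_label, selection_label))
    warning("thresholds are being evaluated on the cohort they were selected on")
  if (inherits(thresholds_list, "threshold_pair"))
    thresholds_list <- list(thresholds_list)
  lapply(seq_along(thresholds_list), function(i) {
    th <- thresholds_list[[i]]
    mk <- function(field) {
      bootstrap_ci(function(d) {
        m <- assisted_metrics(d, th)
        v <- m[[field]]
        if (is.null(v) || is.na(v)) NA_real_ else v
      }, cohort, n_boot = n_boot,
      seed = split_seed(seed, paste0("deploy", i, field)), name = field)
    }
    structure(list(thresholds = th, cohort_label = cohort_label,
                   npv = mk("npv"), ppv = mk("ppv"),
                   reduction = mk("test_reduction")),
              class = "operating_point_report")
  })
}

#' Prevalence implied by a benchmark's sensitivity, specificity and PPV
#'
#' Solves PPV = sens p / (sens p + (1 - spec)(1 - p)) for the prevalence
#' p. At the historical rapid-test values (0.918, 0.993, 0.988) the
#' implied prevalence is ~0.386.
#'
#' @param benchmark an [idylla_benchmark()] object with sens, spec, ppv
#'   strictly inside (0, 1).
#' @return Prevalence in (0, 1).
#' @export
implied_prevalence <- function(benchmark) {
  stopifnot(inherits(benchmark, "benchmark_performance"))
  se <- benchmark$sensitivity; sp <- benchmark$specificity; ppv <- benchmark$ppv
  if (!all(c(se, sp, ppv) > 0 & c(se, sp, ppv) < 1))
    stop("sensitivity, specificity and PPV must lie strictly inside (0, 1)")
  p <- ppv * (1 - sp) / (se * (1 - ppv) + ppv * (1 - sp))
  if (!(p > 0 && p < 1)) stop("inconsistent benchmark: no prevalence in (0, 1)")
  p
}

#' Write triage surfaces as a long-format CSV
#'
#' Columns: t_neg, t_pos, npv, ppv, reduction, n_neg, n_pos.
#' @param surfaces a [grid_evaluate()] result.
#' @param path output CSV path.
#' @export
write_surfaces <- function(surfaces, path) {
  stopifnot(inherits(surfaces, "triage_surfaces"))
  df <- expand.grid(t_neg = surfaces$t_neg, t_pos = surfaces$t_pos)
  df$npv <- as.vector(surfaces$npv)
  df$ppv <- as.vector(surfaces$ppv)
  df$reduction <- as.vector(surfaces$reduction)
  df$n_neg <- as.vector(surfaces$n_neg)
  df$n_pos <- as.vector(surfaces$n_pos)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render the test-reduction heatmap with benchmark isolines
#'
#' Writes a PNG showing the rapid-test reduction surface over the
#' threshold grid, with isolines at the benchmark NPV and PPV values.
#'
#' @param surfaces a [grid_evaluate()] result.
#' @param benchmark an [idylla_benchmark()] object.
#' @param path output PNG path.
#' @export
plot_triage_surfaces <- function(surfaces, benchmark, path) {
  grDevices::png(path, width = 800, height = 700)
  on.exit(grDevices::dev.off())
  graphics::image(surfaces$t_neg, surfaces$t_pos, surfaces$reduction,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "NPV threshold (t_neg)", ylab = "PPV threshold (t_pos)",
                  main = "Rapid-test reduction")
  npv_s <- surfaces$npv; npv_s[is.na(npv_s)] <- 0
  ppv_s <- surfaces$ppv; ppv_s[is.na(ppv_s)] <- 0
  graphics::contour(surfaces$t_neg, surfaces$t_pos, npv_s,
                    levels = benchmark$npv, col = "white", lwd = 2, add = TRUE)
  graphics::contour(surfaces$t_neg, surfaces$t_pos, ppv_s,
                    levels = benchmark$ppv, col = "red", lwd = 2, add = TRUE)
  invisible(path)
}

#' Write operating-point reports as JSON
#'
#' Mirrors a deployment-report table: one entry per threshold pair with
#' NPV/PPV/reduction point estimates and 95% CIs.
#'
#' @param reports list from [evaluate_deployment()].
#' @param path output JSON path.
#' @export
write_deployment_report <- function(reports, path) {
  out <- lapply(reports, function(r) {
    est <- function(e) list(point = e$point, ci_low = e$ci_low,
                            ci_high = e$ci_high)
    list(t_neg = r$thresholds$t_neg, t_pos = r$thresholds$t_pos,
         cohort = r$cohort_label,
         npv = est(r$npv), ppv = est(r$ppv), reduction = est(r$reduction))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
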