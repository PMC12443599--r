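test_that("the three-branch screening rule and its boundaries", {
  th <- threshold_pair(0.004, 0.999)
  r <- screen_sample(0.001, th)
  expect_equal(r$call, "negative")
  expect_false(r$rapid_used)

  r2 <- screen_sample(0.5, th, rapid_call = "positive")
  expect_equal(r2$call, "positive")
  expect_true(r2$rapid_used)

  # boundary scores belong to the rapid zone
  r3 <- screen_sample(0.004, th, rapid_call = "negative")
  expect_true(r3$rapid_used)
  r4 <- screen_sample(0.999, th, rapid_call = "negative")
  expect_true(r4$rapid_used)

  expect_error(screen_sample(0.5, th), "rapid test result required")
  expect_error(screen_sample(0.5, th, rapid_call = "not_performed"),
               "rapid test result required")
  expect_error(threshold_pair(0.7, 0.3), "t_neg <= t_pos")
})

test_that("assisted metrics match hand enumeration on an 8-sample cohort", {
  co <- data.frame(
    sample_id = paste0("h", 1:8),
    score = c(0.001, 0.003, 0.20, 0.40, 0.60, 0.9991, 0.9995, 0.50),
    ngs_label = c("wild-type", "mutant", "wild-type", "mutant",
                  "mutant", "mutant", "wild-type", "wild-type"),
    rapid_call = c("negative", "negative", "negative", "positive",
                   "positive", "positive", "positive", "negative"),
    stringsAsFactors = FALSE)
  th <- threshold_pair(0.004, 0.999)
  m <- assisted_metrics(co, th)
  # hand enumeration: AI-neg = s1, s2; AI-pos = s6, s7; rapid zone = rest
  # screen-negatives: s1, s2 (AI), s3, s8 (rapid) -> wild-type 3/4
  # screen-positives: s6, s7 (AI), s4, s5 (rapid) -> mutant 3/4
  expect_equal(m$npv, 3 / 4)
  expect_equal(m$ppv, 3 / 4)
  expect_equal(m$test_reduction, 4 / 8)
  expect_equal(m$n_screen_neg, 4)
  expect_equal(m$n_screen_pos, 4)

  bf <- brute_assisted(co, th)
  expect_equal(m$npv, bf$npv)
  expect_equal(m$ppv, bf$ppv)
  expect_equal(m$test_reduction, bf$test_reduction)
})

test_that("assisted metrics equal per-sample enumeration on random cohorts", {
  for (seed in 1:6) {
    co <- random_cohort(sample(50:500, 1), seed = seed, ties = seed %% 2 == 0)
    th <- threshold_pair(runif(1, 0, 0.3), runif(1, 0.7, 1))
    m <- assisted_metrics(co, th)
    bf <- brute_assisted(co, th)
    expect_equal(m$npv, bf$npv)
    expect_equal(m$ppv, bf$ppv)
    expect_equal(m$test_reduction, bf$test_reduction)
  }
})

test_that("assisted metrics flag empty denominators and missing rapids", {
  co <- data.frame(sample_id = "x", score = 0.9, ngs_label = "mutant",
                   rapid_call = "positive", stringsAsFactors = FALSE)
  m <- assisted_metrics(co, threshold_pair(0.5, 0.5))
  expect_true(is.na(m$npv))
  expect_true("npv_undefined" %in% m$flags)

  co2 <- data.frame(sample_id = "y", score = 0.5, ngs_label = "mutant",
                    rapid_call = "not_performed", stringsAsFactors = FALSE)
  expect_error(assisted_metrics(co2, threshold_pair(0.2, 0.8)),
               "rapid test result missing")
})

test_that("grid surfaces reproduce corner identities and direct calls", {
  co <- random_cohort(400, seed = 9)
  surf <- grid_evaluate(co, t_neg_range = c(0, 0.5), t_pos_range = c(0.5, 1),
                        step = 0.5)  # degenerate 2x2 grid of the corners
  # (0, 1): no reduction, rapid-test-alone metrics
  y <- co$ngs_label == "mutant"
  i0 <- 1; j1 <- 2
  expect_equal(surf$reduction[i0, j1], 0)
  expect_equal(surf$npv[i0, j1], mean(!y[co$rapid_call == "negative"]))
  expect_equal(surf$ppv[i0, j1], mean(y[co$rapid_call == "positive"]))
  # (0.5, 0.5): full replacement, score-alone metrics at cut 0.5
  expect_equal(surf$reduction[2, 1], 1)
  expect_equal(surf$npv[2, 1], mean(!y[co$score < 0.5]))
  expect_equal(surf$ppv[2, 1], mean(y[co$score > 0.5]))

  # random cells equal a direct assisted_metrics call
  surf2 <- grid_evaluate(co, step = 0.05)
  set.seed(2)
  for (rep in 1:10) {
    i <- sample(length(surf2$t_neg), 1); j <- sample(length(surf2$t_pos), 1)
    d <- assisted_metrics(co, threshold_pair(surf2$t_neg[i], surf2$t_pos[j]))
    expect_equal(surf2$npv[i, j], d$npv)
    expect_equal(surf2$ppv[i, j], d$ppv)
    expect_equal(surf2$reduction[i, j], d$test_reduction)
    expect_equal(surf2$n_neg[i, j], d$n_screen_neg)
    expect_equal(surf2$n_pos[i, j], d$n_screen_pos)
  }

  # reduction monotone along each threshold axis (skipped-set inclusion)
  expect_true(all(diff(surf2$reduction) >= 0))        # t_neg increasing
  expect_true(all(t(apply(surf2$reduction, 1, diff)) <= 0))  # t_pos increasing

  expect_error(grid_evaluate(co, t_neg_range = c(0, 0.7)), "ranges")
  co_np <- co; co_np$rapid_call[3] <- "not_performed"
  expect_error(grid_evaluate(co_np, step = 0.1), "required")
})

test_that("noninferiority region is an elementwise benchmark comparison", {
  co <- random_cohort(400, seed = 13)
  surf <- grid_evaluate(co, step = 0.05)
  all_true <- noninferiority_region(surf, idylla_benchmark(0, 0, 0, 0))
  expect_true(all(all_true))

  none <- noninferiority_region(surf, idylla_benchmark(1, 1, 1, 1))
  expect_identical(unname(none), unname(!is.na(surf$npv) & surf$npv == 1 &
                                          !is.na(surf$ppv) & surf$ppv == 1))

  bench <- idylla_benchmark(0.9, 0.95, 0.9, 0.9)
  reg <- noninferiority_region(surf, bench, margin = 0.02)
  oracle <- surf$npv >= 0.9 - 0.02 & surf$ppv >= 0.9 - 0.02
  oracle[is.na(oracle)] <- FALSE
  expect_identical(unname(reg), unname(oracle))

  # CI-lower-bound mode loosens the cut
  reg_ci <- noninferiority_region(surf, bench, mode = "ci_lower",
                                  benchmark_ci = list(npv_low = 0.85,
                                                      ppv_low = 0.85))
  expect_true(all(reg_ci >= reg))
})

test_that("operating-point selection is a constrained exhaustive maximum", {
  co <- random_cohort(600, seed = 17)
  surf <- grid_evaluate(co, step = 0.02)
  bench <- idylla_benchmark(0.9, 0.95, 0.8, 0.85)
  reg <- noninferiority_region(surf, bench)
  expect_gt(sum(reg), 0)

  # k = 1 on an all-true region: the global max-reduction cell
  all_reg <- matrix(TRUE, length(surf$t_neg), length(surf$t_pos))
  p1 <- select_operating_points(surf, all_reg, bench, k = 1)
  expect_equal(p1[[1]]$reduction, max(surf$reduction))

  pts <- select_operating_points(surf, reg, bench, k = 3)
  reds <- vapply(pts, function(p) p$reduction, numeric(1))
  expect_true(all(diff(reds) > 0))
  # brute-force check: each point maximizes min-slack at its level
  for (p in pts) {
    cells <- which(reg & abs(surf$reduction - p$reduction) < 1e-12)
    slack <- pmin(surf$npv[cells] - bench$npv, surf$ppv[cells] - bench$ppv)
    expect_equal(min(p$npv - bench$npv, p$ppv - bench$ppv), max(slack))
  }

  # single feasible cell: returned for k = 1, error beyond
  single <- matrix(FALSE, length(surf$t_neg), length(surf$t_pos))
  single[3, 4] <- TRUE
  s1 <- select_operating_points(surf, single, bench, k = 1)
  expect_equal(s1[[1]]$t_neg, surf$t_neg[3])
  expect_equal(s1[[1]]$t_pos, surf$t_pos[4])
  expect_error(select_operating_points(surf, single, bench, k = 2),
               "strictly increasing")
  empty <- matrix(FALSE, length(surf$t_neg), length(surf$t_pos))
  expect_error(select_operating_points(surf, empty, bench), "no noninferior")
})

test_that("deployment evaluation is seeded, CI-consistent, leakage-guarded", {
  co <- random_cohort(800, seed = 23)
  th <- list(threshold_pair(0.05, 0.97))
  r1 <- evaluate_deployment(co, th, n_boot = 200, seed = 4)
  r2 <- evaluate_deployment(co, th, n_boot = 200, seed = 4)
  expect_identical(r1[[1]]$npv[c("ci_low", "ci_high")],
                   r2[[1]]$npv[c("ci_low", "ci_high")])

  expect_warning(
    evaluate_deployment(co, th, n_boot = 50, seed = 1,
                        cohort_label = "pretrial", selection_label = "pretrial"),
    "selected on")

  # large-cohort point estimates match cohort-level truth within the CI
  big <- simulate_cohort(score_model_params(20000, 0.39, 0.89, seed = 31))
  thb <- threshold_pair(0.03, 0.99)
  truth <- assisted_metrics(big, thb)
  rb <- evaluate_deployment(big, list(thb), n_boot = 200, seed = 7)[[1]]
  expect_equal(rb$npv$point, truth$npv)
  expect_true(rb$npv$ci_low <= truth$npv && truth$npv <= rb$npv$ci_high)
  expect_true(rb$reduction$ci_low <= truth$test_reduction &&
                truth$test_reduction <= rb$reduction$ci_high)
})

test_that("implied prevalence inverts the PPV identity", {
  expect_equal(implied_prevalence(idylla_benchmark(0.5, 0.5, 0.5, 0.5)), 0.5)
  p <- implied_prevalence(idylla_benchmark())
  expect_equal(p, 0.386, tolerance = 0.001)

  # closure: simulate at the implied prevalence, recover the input PPV
  n <- 1e6
  labels <- ifelse(with_seed(41, runif(n)) < p, "mutant", "wild-type")
  calls <- simulate_rapid_test(labels, rapid_test_params(0.918, 0.993, seed = 42))
  emp_ppv <- mean(labels[calls == "positive"] == "mutant")
  expect_equal(emp_ppv, 0.988, tolerance = 0.005)

  expect_error(implied_prevalence(idylla_benchmark(1, 0.993, 0.988, 0.954)),
               "strictly inside")
})

test_that("self-consistent benchmark derives PPV and NPV by Bayes' rule", {
  b <- benchmark_from_params(0.918, 0.993, 0.3857)
  expect_equal(b$ppv, 0.988, tolerance = 0.0005)
  expect_equal(b$npv, 0.9507, tolerance = 0.0005)
  # PPV round-trips through implied_prevalence
  expect_equal(implied_prevalence(b), 0.3857, tolerance = 1e-9)
})

test_that("surfaces serialize to long CSV and a heatmap renders", {
  co <- random_cohort(200, seed = 3)
  surf <- grid_evaluate(co, step = 0.1)
  f <- tempfile(fileext = ".csv")
  write_surfaces(surf, f)
  df <- read.csv(f)
  expect_equal(nrow(df), length(surf$t_neg) * length(surf$t_pos))
  i <- 3; j <- 2
  row <- df[df$t_neg == surf$t_neg[i] & df$t_pos == surf$t_pos[j], ]
  expect_equal(row$reduction, surf$reduction[i, j])

  p <- tempfile(fileext = ".png")
  plot_triage_surfaces(surf, idylla_benchmark(), p)
  expect_true(file.size(p) > 0)
})
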