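test_that("AUROC equals the brute-force pairwise win fraction", {
  # worked example: positives {0.9, 0.7}, negatives {0.8, 0.2}
  expect_equal(auroc_ci(c(0.9, 0.7, 0.8, 0.2), c(1, 1, 0, 0))$auroc, 0.75)
  # perfect separation
  expect_equal(auroc_ci(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auroc, 1)
  # random small instances, ties included
  for (i in 1:30) {
    withr::with_seed(5000 + i, {
      n <- sample(6:50, 1)
      labels <- rbinom(n, 1, 0.4)
      if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
      scores <- round(runif(n), 2)   # rounding forces ties
    })
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    wins <- 0
    for (a in pos) for (b in neg) {
      wins <- wins + (a > b) + 0.5 * (a == b)
    }
    oracle <- wins / (length(pos) * length(neg))
    est <- auroc_ci(scores, labels)
    expect_equal(est$auroc, oracle, tolerance = 1e-12)
    expect_true(est$lower <= est$auroc && est$auroc <= est$upper)
  }
  expect_error(auroc_ci(runif(5), rep(1, 5)), class = "hoofpspm_undefined")
})

test_that("null scores give AUROC near one half", {
  withr::with_seed(77, {
    scores <- runif(4000); labels <- rbinom(4000, 1, 0.5)
  })
  expect_lt(abs(auroc_ci(scores, labels)$auroc - 0.5), 0.03)
})

test_that("sensitivity and specificity match their defining counts", {
  perfect <- sens_spec_at_cutoff(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect$estimate, c(100, 100))
  flipped <- sens_spec_at_cutoff(c(0, 0, 1, 1), c(1, 1, 0, 0))
  expect_equal(flipped$estimate, c(0, 0))
  # 7 of 12 positives called, 80 of 82 negatives clear
  scores <- c(rep(0.9, 7), rep(0.1, 5), rep(0.2, 80), rep(0.8, 2))
  labels <- rep(c(1L, 0L), c(12, 82))
  ss <- sens_spec_at_cutoff(scores, labels, cutoff = 0.5)
  expect_equal(ss$estimate, c(100 * 7 / 12, 100 * 80 / 82), tolerance = 1e-9)
  expect_equal(round(ss$estimate, 1), c(58.3, 97.6))
  # missing class leaves that metric undefined
  ss2 <- sens_spec_at_cutoff(c(0.9, 0.2), c(1, 1))
  expect_true(is.na(ss2$estimate[ss2$metric == "specificity"]))
})

test_that("Wald proportion intervals reproduce the reporting arithmetic", {
  r <- function(x) round(unlist(x))
  expect_equal(r(wald_ci_proportion(12, 94)),
               c(percent = 13, lower = 6, upper = 20))
  expect_equal(r(wald_ci_proportion(14, 94)),
               c(percent = 15, lower = 8, upper = 22))
  expect_equal(r(wald_ci_proportion(80, 94)),
               c(percent = 85, lower = 78, upper = 92))
  ci <- wald_ci_proportion(1, 12)   # bounds are deliberately untruncated
  expect_equal(round(c(ci$percent, ci$lower, ci$upper)), c(8, -7, 24))
  expect_equal(unlist(wald_ci_proportion(0, 10)),
               c(percent = 0, lower = 0, upper = 0))
  expect_error(wald_ci_proportion(1, 0), class = "hoofpspm_invalid_config")
})

test_that("proportion summaries render in the house style", {
  expect_identical(format_proportion_summary(12, 94),
                   "12/94 (13% 95% CI 6; 20)")
  expect_identical(format_proportion_summary(80, 94),
                   "80/94 (85% 95% CI 78; 92)")
  expect_identical(format_proportion_summary(0, 10),
                   "0/10 (0% 95% CI 0; 0)")
  expect_identical(format_proportion_summary(3, 12),
                   "3/12 (25% 95% CI 0.5; 50)")
})

test_that("Hosmer-Lemeshow detects miscalibration and not exact fits", {
  # constant-risk model on homogeneous data is exactly calibrated
  withr::with_seed(91, y <- rbinom(400, 1, 0.3))
  expect_warning(hl0 <- hosmer_lemeshow(rep(mean(y), 400), y),
                 class = "hoofpspm_hl_merged")
  expect_lt(hl0$statistic, 1e-9)
  # a well-specified refit keeps the statistic near its df
  cfg <- cohort_config(n_feet = 3000, seed = 92)
  rec <- simulate_measure_cohort(cfg)
  fit <- fit_logistic(rec, names(cfg$coefficients))
  hl1 <- hosmer_lemeshow(fit)
  expect_identical(hl1$df, 8L)
  expect_lt(hl1$statistic, 30)
  # omitting a strong covariate inflates the statistic
  fit_bad <- fit_logistic(rec, "HL_med")
  hl2 <- hosmer_lemeshow(fit_bad)
  expect_gt(hl2$statistic, hl1$statistic)
  expect_error(hosmer_lemeshow(runif(10), rbinom(10, 1, 0.5), groups = 2),
               class = "hoofpspm_invalid_config")
})

test_that("evaluate_model bundles calibration and discrimination", {
  cfg <- cohort_config(n_feet = 800, seed = 93)
  rec <- simulate_measure_cohort(cfg)
  fit <- fit_logistic(rec, names(cfg$coefficients))
  ev <- evaluate_model(fit)
  expect_s3_class(ev, "model_eval")
  expect_true(ev$auroc$auroc > 0.5 && ev$auroc$auroc <= 1)
  gl <- glance(ev)
  expect_true(all(c("hl_statistic", "auroc", "sensitivity",
                    "specificity") %in% names(gl)))
  rc <- roc_curve_data(fit)
  expect_true(all(diff(rc$sensitivity) <= 1e-9))
})
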