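test_that("percentage difference arithmetic and guards", {
  expect_equal(percent_difference(10, 9), -10)
  expect_equal(percent_difference(8, 8.4), 5)
  expect_equal(percent_difference(3.7, 3.7), 0)
  expect_equal(percent_difference(c(10, 8), c(9, 8.4)), c(-10, 5))
  expect_error(percent_difference(0, 5), class = "hoofpspm_invalid_measure")
  expect_error(percent_difference(-2, 5), class = "hoofpspm_invalid_measure")
})

test_that("Bonferroni adjustment reports exact and display levels", {
  ba <- bonferroni_alpha(0.05, 18)
  expect_equal(ba$display, 0.003)
  expect_equal(ba$exact, 0.05 / 18, tolerance = 1e-12)
  expect_equal(bonferroni_alpha(0.05, 1)$exact, 0.05)
  expect_equal(bonferroni_alpha(0.10, 4)$exact, 0.025)
  expect_error(bonferroni_alpha(0.05, 0), class = "hoofpspm_invalid_config")
})

test_that("raw measurement tables convert to percentage-difference records", {
  cfg <- cohort_config(n_feet = 40, seed = 2)
  rec <- simulate_measure_cohort(cfg)
  tab <- simulate_measure_table(rec, seed = 3)
  # all lengths positive, all angles within (0, 90)
  hm <- hoof_measures()
  for (m in hm$measure[hm$kind == "angle"]) {
    expect_true(all(tab[[m]] > 0 & tab[[m]] < 90))
  }
  for (m in hm$measure[hm$kind == "length"]) expect_true(all(tab[[m]] > 0))
  rec2 <- percent_diff_records(tab, outcomes = rec[, c("foot_id", "outcome")])
  for (m in hm$measure) expect_equal(rec2[[m]], rec[[m]], tolerance = 1e-9)
  expect_identical(rec2$outcome, rec$outcome)
  expect_error(percent_diff_records(tab[tab$condition == "before", ]),
               class = "hoofpspm_format")
})

test_that("univariable screen routes tests and flags Bonferroni survivors", {
  rec <- simulate_group_cohort(n_pos = 12, n_neg = 82,
                               shifts = c(HA_lat = 16), seed = 11)
  scr <- univariable_screen(rec)
  expect_identical(nrow(scr), 18L)
  expect_true(all(scr$test %in% c("t", "rank-sum")))
  ha <- scr[scr$measure == "HA_lat", ]
  expect_true(ha$significant_bonferroni)
  # the planted shift dominates: no more than one other measure survives
  expect_lte(sum(scr$significant_bonferroni), 2L)
})

test_that("identical outcome groups give p = 1 on either route", {
  vals <- c(1.2, -0.5, 3.4, 0.8, -2.2, 1.9)
  rec <- tibble::tibble(BBL = c(vals, vals),
                        outcome = rep(c(1L, 0L), each = 6))
  scr <- univariable_screen(rec, measures = "BBL", m = 1)
  expect_equal(scr$p_value, 1, tolerance = 1e-9)
})

test_that("a constant measure yields an undefined-test signal", {
  rec <- tibble::tibble(BBL = rep(2.5, 20),
                        outcome = rep(c(1L, 0L), 10))
  scr <- univariable_screen(rec, measures = "BBL", m = 1)
  expect_identical(scr$test, "undefined")
  expect_true(is.na(scr$p_value))
  expect_false(scr$significant_bonferroni)
})

test_that("univariable screen holds its nominal type-I error under the null", {
  reps <- 300
  hits <- 0
  for (i in seq_len(reps)) {
    withr::with_seed(2000 + i, {
      rec <- tibble::tibble(BBL = rnorm(94, 0, 5),
                            outcome = rep(c(1L, 0L), c(12, 82)))
    })
    scr <- univariable_screen(rec, measures = "BBL", m = 1)
    if (scr$p_value < 0.05) hits <- hits + 1
  }
  expect_lt(abs(hits / reps - 0.05), 0.03)
})

test_that("correlation screen drops exactly one member of collinear pairs", {
  withr::with_seed(31, {
    x <- rnorm(94); z <- rnorm(94)
  })
  # exact sample correlation by Gram-Schmidt: r = 0.79 stays, r = 1 drops
  zo <- residuals(lm(z ~ x))
  mk <- function(r) r * scale(x)[, 1] + sqrt(1 - r^2) * scale(zo)[, 1]
  rec <- tibble::tibble(
    BBL = x, W = x,                      # perfect copy
    HA_lat = mk(0.79), HL_med = rnorm(94))
  out <- correlation_screen(rec, measures = c("BBL", "W", "HA_lat", "HL_med"),
                            threshold = 0.8,
                            priority = c(BBL = 0.01, W = 0.5))
  expect_identical(out$dropped, "W")            # smaller priority p kept
  expect_true(all(c("BBL", "HA_lat", "HL_med") %in% out$retained))
  expect_identical(nrow(out$pairs), 1L)
  # strict inequality at the threshold: the 0.79 pair is retained
  r_obs <- abs(cor(rec$BBL, rec$HA_lat))
  expect_lt(r_obs, 0.8)
})

test_that("independent measures are rarely pruned at n = 94", {
  drops <- vapply(1:40, function(i) {
    withr::with_seed(3000 + i, {
      rec <- tibble::as_tibble(
        setNames(as.data.frame(matrix(rnorm(94 * 6), 94)),
                 c("BBL", "W", "HA_lat", "HL_med", "HB_COP", "COR_T")))
    })
    length(correlation_screen(
      rec, measures = names(rec), threshold = 0.8)$dropped)
  }, numeric(1))
  expect_gt(mean(drops == 0), 0.95)
})
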