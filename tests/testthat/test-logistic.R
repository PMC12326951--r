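test_that("intercept-only fit equals the log odds of the event rate", {
  rec <- tibble::tibble(outcome = rep(c(1L, 0L), c(12, 82)))
  fit <- fit_logistic(rec)
  expect_equal(unname(coef(fit$fit)[1]), log(12 / 82), tolerance = 1e-8)
  expect_identical(fit$n_events, 12L)
})

test_that("degenerate designs raise classed signals", {
  rec <- tibble::tibble(BBL = rep(0, 30), outcome = rep(c(1L, 0L), 15))
  expect_error(fit_logistic(rec, "BBL"),
               class = "hoofpspm_degenerate_covariate")
  withr::with_seed(41, {
    sep <- tibble::tibble(BBL = c(rnorm(15, 5), rnorm(15, -5)),
                          outcome = rep(c(1L, 0L), each = 15))
  })
  err <- tryCatch(fit_logistic(sep, "BBL"), error = function(e) e)
  expect_s3_class(err, "hoofpspm_separation")
  expect_identical(err$variable, "BBL")
})

test_that("fits recover the generating coefficients on a large cohort", {
  cfg <- cohort_config(n_feet = 5000, seed = 51)
  rec <- simulate_measure_cohort(cfg)
  fit <- fit_logistic(rec, names(cfg$coefficients))
  truth <- c(cfg$intercept, cfg$coefficients)
  cf <- fit$coefficients
  expect_identical(cf$term, c("(Intercept)", names(cfg$coefficients)))
  expect_true(all(abs(cf$estimate - truth) <= 3 * cf$std.error))
})

test_that("odds ratios reconstruct the published measure effects", {
  # bearing border length: coefficient -0.41 (SE 0.13)
  expect_equal(odds_ratio_ci(-0.41, 0.13), list(or = 0.66, lower = 0.51,
                                                upper = 0.86))
  # heel-buttress-to-centre-of-pressure distance: 0.26 (SE 0.09)
  or2 <- odds_ratio_ci(0.26, 0.09)
  expect_equal(or2$or, 1.30)
  expect_equal(or2$lower, 1.09)
  expect_equal(or2$upper, 1.55)
  # null coefficient: OR 1 with a log-symmetric interval
  or0 <- odds_ratio_ci(0, 0.2, round_digits = NULL)
  expect_equal(or0$or, 1)
  expect_equal(or0$lower * or0$upper, 1, tolerance = 1e-12)
  expect_error(odds_ratio_ci(0.2, 0), class = "hoofpspm_invalid_config")
})

test_that("model invariants hold: lower < OR < upper, width grows with SE", {
  wide <- odds_ratio_ci(0.3, 0.5, round_digits = NULL)
  narrow <- odds_ratio_ci(0.3, 0.1, round_digits = NULL)
  for (o in list(wide, narrow)) {
    expect_lt(o$lower, o$or); expect_lt(o$or, o$upper)
  }
  expect_gt(wide$upper - wide$lower, narrow$upper - narrow$lower)
})

test_that("forward LR selection obeys its entry threshold semantics", {
  withr::with_seed(61, {
    rec <- tibble::tibble(
      BBL = rnorm(94),
      outcome = rep(c(1L, 0L), c(12, 82)))
    rec$BBL <- rec$BBL + 0.55 * rec$outcome   # modest single candidate
  })
  null_ll <- fit_logistic(rec)$logLik
  alt_ll <- fit_logistic(rec, "BBL")$logLik
  p_cand <- pchisq(2 * (alt_ll - null_ll), 1, lower.tail = FALSE)
  sel_in <- forward_lr_select(rec, "BBL", p_enter = p_cand + 0.01)
  expect_identical(sel_in$variables, "BBL")
  expect_identical(sel_in$trace$action, "add")
  sel_out <- forward_lr_select(rec, "BBL", p_enter = p_cand / 2)
  expect_identical(sel_out$variables, character(0))
  expect_identical(nrow(sel_out$trace), 0L)
})

test_that("selection recovers planted signals among noise candidates", {
  cfg <- cohort_config(n_feet = 2000, seed = 71)
  rec <- simulate_measure_cohort(cfg)
  pool <- c(names(cfg$coefficients),
            c("LHWL", "MHWA", "W", "COR_T", "DHWA_med", "FRA_T", "LHWA",
              "COP_COR"))
  sel <- forward_lr_select(rec, pool)
  expect_true(all(names(cfg$coefficients) %in% sel$variables))
  expect_lte(length(setdiff(sel$variables, names(cfg$coefficients))), 1L)
  # final model variables stay inside the candidate pool
  expect_true(all(sel$variables %in% pool))
})

test_that("an empty candidate pool returns an annotated intercept-only model", {
  rec <- tibble::tibble(outcome = rep(c(1L, 0L), c(5, 20)))
  sel <- forward_lr_select(rec, character(0))
  expect_identical(sel$variables, character(0))
  expect_match(attr(sel, "note"), "intercept-only")
})

test_that("predicted probabilities follow the reference equation", {
  ref <- frog_risk_model()
  p0 <- predict_probability(ref, list(BBL = 0, HB_COP = 0, HA_lat = 0,
                                      HL_med = 0))
  expect_equal(p0, exp(-6.29) / (1 + exp(-6.29)), tolerance = 1e-12)
  expect_equal(p0, 0.00185, tolerance = 1e-2)
  # x = 0 gives P = 0.5
  flat <- list(intercept = 0, coefficients = c(BBL = 0.3))
  expect_equal(predict_probability(flat, list(BBL = 0)), 0.5)
  # monotone in each input with the coefficient's sign
  base <- list(BBL = 1, HB_COP = 2, HA_lat = 3, HL_med = -1)
  p_base <- predict_probability(ref, base)
  up <- function(v, d = 1) { b <- base; b[[v]] <- b[[v]] + d; b }
  expect_lt(predict_probability(ref, up("BBL")), p_base)
  expect_gt(predict_probability(ref, up("HA_lat")), p_base)
  expect_gt(predict_probability(ref, up("HB_COP")), p_base)
  expect_lt(predict_probability(ref, up("HL_med")), p_base)
  expect_error(predict_probability(ref, list(BBL = 1)),
               class = "hoofpspm_input_contract")
})

test_that("tidiers expose coefficient and model-level summaries", {
  cfg <- cohort_config(n_feet = 300, seed = 81)
  rec <- simulate_measure_cohort(cfg)
  fit <- fit_logistic(rec, c("BBL", "HA_lat"))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "odds.ratio",
                    "conf.low", "conf.high") %in% names(td)))
  expect_equal(td$odds.ratio, exp(td$estimate), tolerance = 1e-9)
  expect_true(all(td$conf.low < td$odds.ratio & td$odds.ratio < td$conf.high))
  gl <- glance(fit)
  expect_identical(gl$n, 300L)
  expect_identical(gl$n_selected, 2L)
})
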