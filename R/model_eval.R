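# Calibration, discrimination and classification summaries for the fitted
# frog-pressure model, plus the Wald proportion interval used in reporting.

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Bins observations into groups by deciles of predicted risk and compares
#' observed with expected event counts:
#' `C = sum (O_g - E_g)^2 / (E_g (1 - E_g / n_g))`, referred to a
#' chi-square with `groups - 2` degrees of freedom.  Duplicate decile
#' boundaries (heavily tied risks) merge bins, with a warning.
#'
#' @param fitted Predicted probabilities, or a `hoof_logit` (its fitted
#'   values are used).
#' @param outcome 0/1 outcomes (not needed when `fitted` is a model).
#' @param groups Number of risk groups (>= 3, default 10).
#' @return List with `statistic`, `df`, `p_value`, `groups` and a `table`
#'   tibble (bin, n, observed, expected, mean risk).
#' @export
hosmer_lemeshow <- function(fitted, outcome = NULL, groups = 10L) {
  if (inherits(fitted, "hoof_logit")) {
    outcome <- fitted$fit$y
    fitted <- stats::fitted(fitted$fit)
  }
  if (groups < 3L) {
    stop_hoofpspm("`groups` must be at least 3.", "hoofpspm_invalid_config")
  }
  stopifnot(length(fitted) == length(outcome))
  brk <- unique(quantile(fitted, probs = seq(0, 1, length.out = groups + 1)))
  if (length(brk) < groups + 1) {
    warn("tied risk deciles; bins merged.", class = "hoofpspm_hl_merged")
  }
  if (length(brk) < 4L) {
    # essentially constant risk: exact calibration check against the mean
    brk <- c(-Inf, Inf)
  }
  bin <- cut(fitted, breaks = brk, include.lowest = TRUE)
  tab <- tibble(bin = bin, fitted = fitted, outcome = outcome) |>
    group_by(.data$bin) |>
    summarise(n = n(), observed = sum(.data$outcome),
              expected = sum(.data$fitted),
              mean_risk = mean(.data$fitted), .groups = "drop")
  g <- nrow(tab)
  denom <- tab$expected * (1 - tab$expected / tab$n)
  ok <- denom > 1e-12
  statistic <- sum((tab$observed[ok] - tab$expected[ok])^2 / denom[ok])
  df <- max(g - 2L, 1L)
  list(statistic = statistic, df = df,
       p_value = pchisq(statistic, df, lower.tail = FALSE),
       groups = g, table = tab)
}

#' AUROC with 95% confidence interval
#'
#' Area under the receiver-operating-characteristic curve: the probability
#' that a randomly chosen event foot receives a higher predicted risk than
#' a randomly chosen non-event foot (ties count one half).  The interval is
#' DeLong's paired large-sample method.
#'
#' @param scores Predicted risks.
#' @param labels 0/1 outcomes (both classes required).
#' @return List with `auroc`, `lower`, `upper`.
#' @export
#' @examples
#' auroc_ci(c(0.9, 0.7, 0.8, 0.2), c(1, 1, 0, 0))$auroc  # 0.75
auroc_ci <- function(scores, labels) {
  if (length(unique(labels)) != 2L) {
    stop_hoofpspm("both outcome classes must be present.",
                  "hoofpspm_undefined")
  }
  roc <- pROC::roc(response = labels, predictor = scores,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  # pROC warns that a degenerate AUC of exactly 1 has a degenerate interval;
  # the bounds it returns are still the right ones to report
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(roc, method = "delong")))
  list(auroc = as.numeric(pROC::auc(roc)),
       lower = ci[1], upper = ci[3])
}

#' Sensitivity and specificity at a probability cut-off
#'
#' Predicted-positive means `score >= cutoff`.  Sensitivity and specificity
#' are returned as percentages with binomial Wald 95% confidence intervals
#' (untruncated).
#'
#' @param scores Predicted risks in (0, 1).
#' @param labels 0/1 outcomes.
#' @param cutoff Probability cut-off (default 0.5).
#' @return Tibble with rows `sensitivity` and `specificity`: `k`, `n`,
#'   `estimate` (%), `lower`, `upper`.  A missing class gives `NA` for the
#'   corresponding row.
#' @export
sens_spec_at_cutoff <- function(scores, labels, cutoff = 0.5) {
  check_number(cutoff, "cutoff", 0, 1, TRUE, TRUE)
  pos <- labels == 1; neg <- labels == 0
  pred_pos <- scores >= cutoff
  mk <- function(k, n, what) {
    if (n == 0) {
      return(tibble(metric = what, k = NA_integer_, n = 0L,
                    estimate = NA_real_, lower = NA_real_, upper = NA_real_))
    }
    ci <- wald_ci_proportion(k, n)
    tibble(metric = what, k = k, n = n, estimate = ci$percent,
           lower = ci$lower, upper = ci$upper)
  }
  bind_rows(
    mk(sum(pred_pos & pos), sum(pos), "sensitivity"),
    mk(sum(!pred_pos & neg), sum(neg), "specificity"))
}

#' Wald 95% confidence interval for a proportion
#'
#' `p-hat +/- 1.96 sqrt(p-hat (1 - p-hat) / n)`, expressed in percent and
#' deliberately not truncated to \[0, 100\] (small samples can print bounds
#' below 0 or above 100).
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials (>= 1).
#' @return List with `percent`, `lower`, `upper` (percent scale, unrounded).
#' @export
#' @examples
#' wald_ci_proportion(12, 94)  # ~13% (6; 20)
wald_ci_proportion <- function(k, n) {
  if (!is.numeric(n) || n < 1 || k < 0 || k > n) {
    stop_hoofpspm("need 0 <= k <= n with n >= 1.", "hoofpspm_invalid_config")
  }
  p <- k / n
  half <- 1.96 * sqrt(p * (1 - p) / n)
  list(percent = 100 * p, lower = 100 * (p - half), upper = 100 * (p + half))
}

#' Evaluate a fitted frog-pressure model
#'
#' One-stop evaluation: Hosmer-Lemeshow calibration, AUROC (DeLong 95% CI)
#' and sensitivity/specificity at the probability cut-off.
#'
#' @param model A `hoof_logit`.
#' @param cutoff Probability cut-off for classification (default 0.5).
#' @param hl_groups Hosmer-Lemeshow risk groups.
#' @return List of class `model_eval` with `hl`, `auroc`, `class_table` and
#'   `cutoff`.
#' @export
evaluate_model <- function(model, cutoff = 0.5, hl_groups = 10L) {
  stopifnot(inherits(model, "hoof_logit"))
  scores <- stats::fitted(model$fit)
  y <- model$fit$y
  structure(
    list(hl = hosmer_lemeshow(scores, y, groups = hl_groups),
         auroc = auroc_ci(scores, y),
         class_table = sens_spec_at_cutoff(scores, y, cutoff),
         cutoff = cutoff, scores = scores, labels = y),
    class = "model_eval")
}

#' @export
print.model_eval <- function(x, ...) {
  cat(sprintf("<model_eval> Hosmer-Lemeshow X2 = %.2f (df %d, p = %.2g)\n",
              x$hl$statistic, x$hl$df, x$hl$p_value))
  cat(sprintf("  AUROC %.2f (95%% CI %.2f; %.2f)\n",
              x$auroc$auroc, x$auroc$lower, x$auroc$upper))
  ct <- x$class_table
  cat(sprintf("  at cut-off %.2f: sensitivity %s%%, specificity %s%%\n",
              x$cutoff, fmt_pct(ct$estimate[1]), fmt_pct(ct$estimate[2])))
  invisible(x)
}

#' @method glance model_eval
#' @export
glance.model_eval <- function(x, ...) {
  tibble(hl_statistic = x$hl$statistic, hl_df = x$hl$df,
         hl_p = x$hl$p_value,
         auroc = x$auroc$auroc, auroc_low = x$auroc$lower,
         auroc_high = x$auroc$upper,
         sensitivity = x$class_table$estimate[1],
         specificity = x$class_table$estimate[2],
         cutoff = x$cutoff)
}

# display rounding used in report text: integer percents, one decimal
# below 1%
fmt_pct <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(abs(p) < 1 & p != 0, sprintf("%.1f", p),
                sprintf("%.0f", round(p))))
}
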