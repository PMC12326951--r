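# Percentage-difference analysis of the eighteen external hoof measures:
# ingestion, univariable screening and correlation-based pruning.

#' Percentage difference of a measure after trimming
#'
#' `100 * (after - before) / before`; negative values are reductions after
#' trimming.  Removing the before-trimming scale makes feet of different
#' sized horses comparable.
#'
#' @param before,after Measure values (same units); `before` must be > 0.
#' @return Signed percentage difference (vectorised).
#' @export
#' @examples
#' percent_difference(10, 9)   # -10
#' percent_difference(8, 8.4)  # +5
percent_difference <- function(before, after) {
  if (any(!is.finite(before)) || any(before <= 0)) {
    stop_hoofpspm("`before` values must be positive.",
                  "hoofpspm_invalid_measure")
  }
  100 * (after - before) / before
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha Nominal familywise level.
#' @param m Number of tests (>= 1).
#' @return List with `exact` (alpha/m) and `display` (rounded to 3 dp, the
#'   conventional reporting form).
#' @export
#' @examples
#' bonferroni_alpha(0.05, 18)  # display 0.003, exact 0.002778
bonferroni_alpha <- function(alpha, m) {
  check_number(alpha, "alpha", 0, 1, TRUE, TRUE)
  if (!is.numeric(m) || length(m) != 1L || m < 1) {
    stop_hoofpspm("`m` must be a positive count.", "hoofpspm_invalid_config")
  }
  list(exact = alpha / m, display = round(alpha / m, 3))
}

#' Percentage-difference records from a raw measurement table
#'
#' Converts a long measurement table (one row per foot per condition) into
#' one percentage-difference record per foot, optionally joining an outcome
#' table from the topographic arm.
#'
#' @param measures Tibble/data frame with `foot_id`, `condition`
#'   (`"before"`/`"after"`) and the 18 measure columns.
#' @param outcomes Optional tibble with `foot_id` and `outcome` (0/1).
#' @return A tibble with `foot_id`, the 18 signed percentage differences and
#'   (if supplied) `outcome`.
#' @export
percent_diff_records <- function(measures, outcomes = NULL) {
  vocab <- hoof_measures()$measure
  missing_cols <- setdiff(c("foot_id", "condition", vocab), names(measures))
  if (length(missing_cols)) {
    stop_hoofpspm(paste0("measurement table is missing column(s): ",
                         paste(missing_cols, collapse = ", ")),
                  "hoofpspm_format")
  }
  long <- tidyr::pivot_longer(as_tibble(measures), dplyr::all_of(vocab),
                              names_to = "measure", values_to = "value")
  wide <- tidyr::pivot_wider(long, names_from = "condition",
                             values_from = "value",
                             id_cols = c("foot_id", "measure"))
  if (!all(c("before", "after") %in% names(wide))) {
    stop_hoofpspm("both a before and an after row are required per foot.",
                  "hoofpspm_format")
  }
  wide$pct_diff <- percent_difference(wide$before, wide$after)
  rec <- tidyr::pivot_wider(wide, id_cols = "foot_id",
                            names_from = "measure",
                            values_from = "pct_diff")
  rec <- rec[, c("foot_id", vocab)]
  if (!is.null(outcomes)) {
    rec <- left_join(rec, select(as_tibble(outcomes), "foot_id", "outcome"),
                     by = "foot_id")
  }
  rec
}

#' Univariable screen of the eighteen hoof measures
#'
#' Compares each measure's percentage difference between outcome groups.
#' The test route is chosen per measure: a pooled-variance two-sample t-test
#' when both groups look normal, a Mann-Whitney rank-sum test otherwise
#' (automated normality rule: Shapiro-Wilk p < `normality_alpha` in either
#' group routes to the rank-sum test).  Group summaries are mean (95% CI)
#' on the normal route and median (IQR) otherwise.  Measures significant
#' after Bonferroni correction (`p < alpha/m`) are flagged.
#'
#' @param records Percentage-difference records with an `outcome` column
#'   ([percent_diff_records()], [simulate_measure_cohort()]).
#' @param measures Character vector of measure columns to screen (default:
#'   the 18-measure vocabulary).
#' @param alpha Nominal familywise level for the Bonferroni flag.
#' @param m Number of tests used in the correction (defaults to the number
#'   of screened measures).
#' @param normality_alpha Shapiro-Wilk level of the routing rule.
#' @param welch Use Welch's t-test instead of the pooled-variance test.
#' @return A tibble with one row per measure: `measure`, `test`
#'   (`"t"`/`"rank-sum"`), `p_value`, group summaries
#'   (`neg_summary`, `pos_summary` as formatted strings, plus numeric
#'   centres), `levene_p` (variance-homogeneity check), and
#'   `significant_bonferroni`.  Measures constant in both groups get
#'   `test = "undefined"` and `NA` p.
#' @export
univariable_screen <- function(records, measures = hoof_measures()$measure,
                               alpha = 0.05, m = length(measures),
                               normality_alpha = 0.05, welch = FALSE) {
  stopifnot("outcome" %in% names(records))
  y <- records$outcome
  if (length(unique(y[!is.na(y)])) != 2L) {
    stop_hoofpspm("both outcome groups must be present.",
                  "hoofpspm_insufficient_data")
  }
  adj <- bonferroni_alpha(alpha, m)$exact
  rows <- lapply(measures, function(mm) {
    x <- records[[mm]]
    g1 <- x[y == 1]; g0 <- x[y == 0]
    if (sd(x) < 1e-12 || (sd(g1) < 1e-12 && sd(g0) < 1e-12)) {
      return(tibble(measure = mm, test = "undefined", p_value = NA_real_,
                    neg_centre = mean(g0), pos_centre = mean(g1),
                    neg_summary = NA_character_, pos_summary = NA_character_,
                    levene_p = NA_real_, significant_bonferroni = FALSE))
    }
    normal <- group_normal(g0, normality_alpha) &&
      group_normal(g1, normality_alpha)
    lev_p <- levene_p(g0, g1)
    if (normal) {
      tt <- t.test(g1, g0, var.equal = !welch)
      p <- tt$p.value
      summ <- function(v) {
        se <- sd(v) / sqrt(length(v))
        sprintf("%.1f (%.1f; %.1f)", mean(v),
                mean(v) - 1.96 * se, mean(v) + 1.96 * se)
      }
      test <- "t"
    } else {
      p <- suppressWarnings(wilcox.test(g1, g0, exact = FALSE))$p.value
      summ <- function(v) {
        q <- quantile(v, c(0.25, 0.5, 0.75))
        sprintf("%.1f (%.1f; %.1f)", q[2], q[1], q[3])
      }
      test <- "rank-sum"
    }
    tibble(measure = mm, test = test, p_value = p,
           neg_centre = if (normal) mean(g0) else median(g0),
           pos_centre = if (normal) mean(g1) else median(g1),
           neg_summary = summ(g0), pos_summary = summ(g1),
           levene_p = lev_p,
           significant_bonferroni = is.finite(p) && p < adj)
  })
  bind_rows(rows)
}

group_normal <- function(v, alpha) {
  if (length(v) < 3L || sd(v) < 1e-12) return(TRUE)
  shapiro.test(v)$p.value >= alpha
}

# Brown-Forsythe variant (absolute deviations from the median), reported as
# a homogeneity-of-variance check alongside the routing decision
levene_p <- function(g0, g1) {
  d0 <- abs(g0 - median(g0)); d1 <- abs(g1 - median(g1))
  if (sd(c(d0, d1)) < 1e-12) return(NA_real_)
  t.test(d0, d1, var.equal = TRUE)$p.value
}

#' Prune highly correlated explanatory variables
#'
#' Computes pairwise correlations between candidate measures (Pearson when
#' both measures pass the normality rule, Spearman otherwise) and, for every
#' pair whose |r| exceeds `threshold` (strictly), drops one member.  The
#' deterministic retention rule keeps the variable with the smaller value in
#' `priority` (e.g. univariable p-values — the more plausible predictor);
#' without priorities the earlier column wins.
#'
#' @param records Percentage-difference records.
#' @param measures Candidate measure columns.
#' @param threshold Absolute correlation above which a pair is collinear
#'   (default 0.8; a pair at exactly the threshold is retained).
#' @param priority Optional named numeric; smaller = preferred.
#' @param normality_alpha Shapiro-Wilk level for the Pearson/Spearman route.
#' @return List with `retained` (character), `dropped` (character) and
#'   `pairs` (tibble of flagged pairs with `r`, `method`, `kept`, `dropped`).
#' @export
correlation_screen <- function(records, measures = hoof_measures()$measure,
                               threshold = 0.8, priority = NULL,
                               normality_alpha = 0.05) {
  check_number(threshold, "threshold", 0, 1, TRUE, TRUE)
  normal <- vapply(measures, function(mm) {
    group_normal(records[[mm]], normality_alpha)
  }, logical(1))
  retained <- measures
  pairs <- list()
  if (length(measures) >= 2L) {
    cmb <- combn(measures, 2L)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      if (!(a %in% retained) || !(b %in% retained)) next
      method <- if (normal[[a]] && normal[[b]]) "pearson" else "spearman"
      r <- suppressWarnings(cor(records[[a]], records[[b]], method = method))
      if (is.na(r) || abs(r) <= threshold) next
      pa <- priority[a] %||% NA_real_; pb <- priority[b] %||% NA_real_
      drop <- if (!is.na(pa) && !is.na(pb)) {
        if (pa <= pb) b else a
      } else b
      keep_v <- if (drop == a) b else a
      retained <- setdiff(retained, drop)
      pairs[[length(pairs) + 1L]] <- tibble(
        var1 = a, var2 = b, r = r, method = method,
        kept = keep_v, dropped = drop)
    }
  }
  pairs <- if (length(pairs)) bind_rows(pairs) else
    tibble(var1 = character(), var2 = character(), r = numeric(),
           method = character(), kept = character(), dropped = character())
  list(retained = retained, dropped = setdiff(measures, retained),
       pairs = pairs)
}
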