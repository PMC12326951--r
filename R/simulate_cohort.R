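#' The eighteen external hoof measures
#'
#' Returns the measure vocabulary used throughout the package: names,
#' measurement kind (length in cm or angle in degrees), a plausible raw
#' baseline value for an unshod fore foot, and the default mean/SD of the
#' percentage change after trimming used by the synthetic cohort generator.
#' Lateral and medial variants of dorsal wall length/angle, heel length and
#' heel angle are separate measures, giving eighteen in all.
#'
#' @return A tibble with columns `measure`, `kind`, `baseline`, `pct_mean`,
#'   `pct_sd`.
#' @export
hoof_measures <- function() {
  tibble::tribble(
    ~measure,    ~kind,    ~baseline, ~pct_mean, ~pct_sd,
    "LHWL",      "length",  9.0,      -5.1,       7.4,
    "LHWA",      "angle",  60.0,       1.6,       3.7,
    "MHWL",      "length",  8.5,      -4.4,       8.5,
    "MHWA",      "angle",  60.0,       1.9,       7.6,
    "DHWL_lat",  "length",  9.5,      -5.6,      12.5,
    "DHWA_lat",  "angle",  45.0,      -2.9,       5.3,
    "HL_lat",    "length",  4.5,      -5.7,      24.7,
    "HA_lat",    "angle",  35.0,       2.5,      14.1,
    "DHWL_med",  "length",  9.5,      -6.3,       6.7,
    "DHWA_med",  "angle",  45.0,       3.2,       5.1,
    "HL_med",    "length",  4.5,      -7.2,      29.5,
    "HA_med",    "angle",  35.0,       0.0,      17.6,
    "W",         "length", 12.5,      -2.8,       8.6,
    "BBL",       "length", 13.0,      -0.4,       6.9,
    "COP_COR",   "length",  2.5,      13.5,      57.9,
    "COR_T",     "length",  9.0,       0.1,      12.4,
    "HB_COP",    "length", 10.0,       2.2,      11.1,
    "FRA_T",     "length",  9.0,      -5.4,      10.0
  )
}

#' Configuration for the synthetic measurement cohort
#'
#' Defines a generative logistic model on the percentage-difference scale:
#' covariates are drawn independently per foot from normal distributions
#' (means/SDs default to [hoof_measures()]), and the binary outcome
#' (increased frog pressure after trimming) is Bernoulli with probability
#' `plogis(intercept + sum(coefficients * covariates))`.  Default intercept
#' and coefficients are those of [frog_risk_model()].
#'
#' @param n_feet Number of feet in the cohort.
#' @param intercept Logistic intercept on the log-odds scale.
#' @param coefficients Named numeric vector of log-odds slopes per unit
#'   percentage difference; names must come from the 18-measure vocabulary.
#' @param covariate_means,covariate_sds Optional named numeric vectors
#'   overriding the default percentage-change distribution per measure.
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_feet = 94L,
                          intercept = frog_risk_model()$intercept,
                          coefficients = frog_risk_model()$coefficients,
                          covariate_means = NULL,
                          covariate_sds = NULL,
                          seed = 1L) {
  vocab <- hoof_measures()$measure
  bad <- setdiff(names(coefficients), vocab)
  if (length(bad)) {
    stop_hoofpspm(paste0("unknown covariate name(s): ",
                         paste(bad, collapse = ", ")),
                  "hoofpspm_invalid_config")
  }
  for (v in list(covariate_means, covariate_sds)) {
    if (!is.null(v) && length(setdiff(names(v), vocab))) {
      stop_hoofpspm("covariate mean/SD names must be hoof measures.",
                    "hoofpspm_invalid_config")
    }
  }
  n_feet <- as.integer(n_feet)
  if (n_feet < length(coefficients) + 1L) {
    stop_hoofpspm("`n_feet` must exceed the number of covariates.",
                  "hoofpspm_invalid_config")
  }
  structure(list(n_feet = n_feet, intercept = intercept,
                 coefficients = coefficients,
                 covariate_means = covariate_means,
                 covariate_sds = covariate_sds, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a measurement cohort from a logistic model
#'
#' Draws the eighteen percentage-difference covariates per foot and a binary
#' increased-frog-pressure outcome from the configured logistic model.
#' Records carry the true event probability so calibration checks can use
#' the generative truth.
#'
#' @param config A [cohort_config()].
#' @return A tibble with `foot_id`, one column per measure (signed
#'   percentage difference, negative = reduction after trimming),
#'   `true_prob` and `outcome` (0/1, 1 = increased frog pressure).
#' @export
#' @examples
#' cfg <- cohort_config(n_feet = 200, seed = 7)
#' cohort <- simulate_measure_cohort(cfg)
#' mean(cohort$outcome)
simulate_measure_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  hm <- hoof_measures()
  mu <- setNames(hm$pct_mean, hm$measure)
  sdv <- setNames(hm$pct_sd, hm$measure)
  if (!is.null(config$covariate_means))
    mu[names(config$covariate_means)] <- config$covariate_means
  if (!is.null(config$covariate_sds))
    sdv[names(config$covariate_sds)] <- config$covariate_sds
  n <- config$n_feet
  withr::with_seed(config$seed, {
    X <- vapply(hm$measure, function(m) {
      v <- rnorm(n, mu[m], sdv[m])
      # keep percentage changes physically sensible (a measure cannot lose
      # more than ~90% of itself in one trim); redraw the rare extreme
      while (any(bad <- abs(v) > 90)) v[bad] <- rnorm(sum(bad), mu[m], sdv[m])
      v
    }, numeric(n))
    eta <- config$intercept +
      as.vector(X[, names(config$coefficients), drop = FALSE] %*%
                  config$coefficients)
    p <- plogis(eta)
    y <- rbinom(n, 1L, p)
  })
  out <- as_tibble(X)
  out$foot_id <- sprintf("F%03d", seq_len(n))
  out$true_prob <- p
  out$outcome <- as.integer(y)
  dplyr::relocate(out, "foot_id")
}

#' Simulate a measurement cohort with fixed outcome groups
#'
#' The outcome-design counterpart of [simulate_measure_cohort()]: group
#' sizes are fixed and covariate distributions may differ by outcome group
#' (location shifts on the percentage-difference scale).  Used to emulate
#' designs where a known number of feet developed increased frog pressure
#' and their measures differ by a specified amount.
#'
#' @param n_pos,n_neg Number of outcome-positive / negative feet.
#' @param shifts Named numeric vector: mean percentage-change shift added to
#'   the positive group for the named measures.
#' @param seed Integer seed.
#' @return Same shape as [simulate_measure_cohort()] (without `true_prob`).
#' @export
simulate_group_cohort <- function(n_pos = 12L, n_neg = 82L,
                                  shifts = c(HA_lat = 16), seed = 1L) {
  hm <- hoof_measures()
  bad <- setdiff(names(shifts), hm$measure)
  if (length(bad)) {
    stop_hoofpspm(paste0("unknown covariate name(s): ",
                         paste(bad, collapse = ", ")),
                  "hoofpspm_invalid_config")
  }
  n <- n_pos + n_neg
  y <- c(rep(1L, n_pos), rep(0L, n_neg))
  withr::with_seed(as.integer(seed), {
    X <- vapply(hm$measure, function(m) {
      shift_m <- if (m %in% names(shifts)) shifts[[m]] else 0
      mu <- hm$pct_mean[hm$measure == m] + shift_m * y
      rnorm(n, mu, hm$pct_sd[hm$measure == m])
    }, numeric(n))
  })
  out <- as_tibble(X)
  out$foot_id <- sprintf("F%03d", seq_len(n))
  out$outcome <- y
  dplyr::relocate(out, "foot_id")
}

#' Expand percentage-difference records into raw before/after measures
#'
#' Builds a raw hoof-measurement table (one row per foot per condition, cm
#' and degrees) whose percentage differences reproduce the given records:
#' before-trimming values are drawn around the vocabulary baselines and
#' after-trimming values are `before * (1 + pct/100)`.  This exercises the
#' measurement-ingestion path of the statistics module.
#'
#' @param records Tibble from [simulate_measure_cohort()] or
#'   [simulate_group_cohort()].
#' @param baseline_cv Coefficient of variation of the before-trimming values
#'   around the vocabulary baselines.
#' @param seed Integer seed.
#' @return A tibble with `foot_id`, `condition` and the 18 measure columns.
#' @export
simulate_measure_table <- function(records, baseline_cv = 0.08, seed = 1L) {
  hm <- hoof_measures()
  n <- nrow(records)
  withr::with_seed(as.integer(seed), {
    before <- vapply(seq_len(nrow(hm)), function(j) {
      v <- hm$baseline[j] * exp(rnorm(n, 0, baseline_cv))
      # keep before-trimming angles low enough that no plausible trim can
      # push the after-trimming angle to 90 degrees
      if (hm$kind[j] == "angle") v <- pmin(v, 65)
      v
    }, numeric(n))
  })
  colnames(before) <- hm$measure
  after <- before * (1 + as.matrix(records[, hm$measure]) / 100)
  bind_rows(
    dplyr::bind_cols(tibble(foot_id = records$foot_id, condition = "before"),
                     as_tibble(before)),
    dplyr::bind_cols(tibble(foot_id = records$foot_id, condition = "after"),
                     as_tibble(after))
  ) |> arrange(.data$foot_id, dplyr::desc(.data$condition))
}
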