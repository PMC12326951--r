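# Logistic modelling of increased frog pressure: maximum-likelihood fits,
# forward likelihood-ratio stepwise selection, odds ratios and prediction.

#' Fit a logistic regression for increased frog pressure
#'
#' Maximum-likelihood binomial fit of `outcome` on the named
#' percentage-difference measures, with odds ratios and 95% Wald confidence
#' intervals per variable.  Degenerate designs are flagged: an all-constant
#' covariate yields an undefined-coefficient error naming it, and complete
#' or quasi-complete separation yields a non-convergence error naming the
#' worst-offending variable.
#'
#' @param records Percentage-difference records with an `outcome` column.
#' @param variables Character vector of predictor columns (may be empty for
#'   an intercept-only model).
#' @return An object of class `hoof_logit`: list with the `glm` `fit`,
#'   `variables`, `coefficients` tibble (term, estimate, std.error,
#'   statistic, p.value, odds.ratio, conf.low, conf.high), `logLik`, `n`,
#'   `n_events` and an empty selection `trace`.
#' @export
fit_logistic <- function(records, variables = character()) {
  stopifnot("outcome" %in% names(records))
  y <- records$outcome
  if (length(unique(y)) != 2L) {
    stop_hoofpspm("outcome must contain both classes.",
                  "hoofpspm_insufficient_data")
  }
  if (nrow(records) <= length(variables)) {
    stop_hoofpspm("more observations than predictors are required.",
                  "hoofpspm_insufficient_data")
  }
  const <- variables[vapply(variables,
                            function(v) sd(records[[v]]) < 1e-12, TRUE)]
  if (length(const)) {
    stop_hoofpspm(
      paste0("coefficient undefined for constant covariate(s): ",
             paste(const, collapse = ", ")),
      "hoofpspm_degenerate_covariate", variables = const)
  }
  fml <- if (length(variables)) {
    stats::reformulate(sprintf("`%s`", variables), response = "outcome")
  } else outcome ~ 1
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(fml, data = records, family = binomial()),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg) ||
          grepl("did not converge", msg)) sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  fv <- stats::fitted(fit)
  # separation drives most fitted probabilities to the boundary; a handful
  # of extreme-but-genuine risks must not trip this
  if (sep_warn && length(cf) > 1L &&
      mean(pmin(fv, 1 - fv) < 1e-6) > 0.5) {
    worst <- names(which.max(abs(cf[-1])))
    stop_hoofpspm(
      paste0("complete or quasi-complete separation; offending variable: ",
             gsub("`", "", worst)),
      "hoofpspm_separation", variable = gsub("`", "", worst))
  }
  se <- sqrt(diag(vcov(fit)))
  terms <- gsub("`", "", names(cf))
  or <- t(vapply(seq_along(cf), function(i) {
    unlist(odds_ratio_ci(cf[i], se[i], round_digits = NULL))
  }, numeric(3)))
  coefs <- tibble(
    term = terms, estimate = unname(cf), std.error = unname(se),
    statistic = unname(cf / se),
    p.value = unname(2 * pnorm(-abs(cf / se))),
    odds.ratio = or[, 1], conf.low = or[, 2], conf.high = or[, 3])
  structure(
    list(fit = fit, variables = variables, coefficients = coefs,
         logLik = as.numeric(logLik(fit)), n = nrow(records),
         n_events = sum(y == 1),
         trace = tibble(step = integer(), action = character(),
                        variable = character(), lr_chisq = numeric(),
                        df = integer(), p_value = numeric())),
    class = "hoof_logit"
  )
}

#' Forward likelihood-ratio stepwise selection
#'
#' Builds a logistic model for increased frog pressure by forward selection
#' with likelihood-ratio tests: at each step the candidate whose addition
#' gives the smallest LR p-value enters if `p < p_enter`; after every
#' addition the included variables are re-tested by LR and any with
#' `p >= p_remove` is removed.  Selection stops when no candidate qualifies.
#' The candidate pool is conventionally restricted to measures with
#' univariable p < 0.2 (see `pool_from_screen()` logic in the pipeline).
#'
#' @param records Percentage-difference records with `outcome`.
#' @param candidates Character vector of candidate measures.
#' @param p_enter LR p-value required to enter (default 0.05).
#' @param p_remove LR p-value at or above which an included variable is
#'   removed (default 0.10).
#' @return A `hoof_logit` whose `trace` records each step (step, action,
#'   variable, LR chi-square, df, p).  An empty pool returns the
#'   intercept-only model with a note attribute.
#' @export
forward_lr_select <- function(records, candidates, p_enter = 0.05,
                              p_remove = 0.10) {
  check_number(p_enter, "p_enter", 0, 1, TRUE, TRUE)
  check_number(p_remove, "p_remove", 0, 1, TRUE, FALSE)
  included <- character()
  trace <- list()
  step <- 0L
  if (length(candidates) == 0L) {
    out <- fit_logistic(records, character())
    attr(out, "note") <- "empty candidate pool; intercept-only model"
    return(out)
  }
  # candidates whose fit separates (or is otherwise degenerate) are skipped
  # for that step rather than aborting the search
  ll <- function(vars) {
    tryCatch(fit_logistic(records, vars)$logLik,
             hoofpspm_separation = function(e) NA_real_,
             hoofpspm_degenerate_covariate = function(e) NA_real_)
  }
  ll_cur <- ll(included)
  repeat {
    pool <- setdiff(candidates, included)
    if (!length(pool)) break
    adds <- vapply(pool, function(v) {
      lr <- 2 * (ll(c(included, v)) - ll_cur)
      c(lr, pchisq(lr, df = 1, lower.tail = FALSE))
    }, numeric(2))
    adds[2, is.na(adds[2, ])] <- Inf
    best <- which.min(adds[2, ])
    if (adds[2, best] >= p_enter) break
    step <- step + 1L
    included <- c(included, pool[best])
    ll_cur <- ll(included)
    trace[[length(trace) + 1L]] <- tibble(
      step = step, action = "add", variable = pool[best],
      lr_chisq = adds[1, best], df = 1L, p_value = adds[2, best])
    # backward LR check of everything currently included
    repeat {
      if (length(included) < 2L) break
      rem <- vapply(included, function(v) {
        lr <- 2 * (ll_cur - ll(setdiff(included, v)))
        c(lr, pchisq(lr, df = 1, lower.tail = FALSE))
      }, numeric(2))
      rem[2, is.na(rem[2, ])] <- 0   # unfittable reduced model: keep the term
      worst <- which.max(rem[2, ])
      if (rem[2, worst] < p_remove) break
      step <- step + 1L
      vdrop <- included[worst]
      included <- setdiff(included, vdrop)
      ll_cur <- ll(included)
      trace[[length(trace) + 1L]] <- tibble(
        step = step, action = "remove", variable = vdrop,
        lr_chisq = rem[1, worst], df = 1L, p_value = rem[2, worst])
    }
  }
  out <- fit_logistic(records, included)
  out$trace <- if (length(trace)) bind_rows(trace) else out$trace
  out
}

#' Odds ratio with 95% Wald confidence interval
#'
#' @param coefficient Log-odds coefficient.
#' @param se Its standard error (> 0).
#' @param round_digits Digits for display rounding (default 2; `NULL` for
#'   unrounded).
#' @return List with `or`, `lower`, `upper`.
#' @export
#' @examples
#' odds_ratio_ci(-0.41, 0.13)  # OR 0.66 (0.51; 0.86)
odds_ratio_ci <- function(coefficient, se, round_digits = 2) {
  check_number(se, "se", 0, strict_lower = TRUE)
  out <- list(or = exp(coefficient),
              lower = exp(coefficient - 1.96 * se),
              upper = exp(coefficient + 1.96 * se))
  if (!is.null(round_digits)) out <- lapply(out, round, round_digits)
  out
}

#' The reference prediction equation for increased frog pressure
#'
#' The package's reference multivariable equation relating percentage
#' differences of four hoof measures to the probability of increased frog
#' pressure after trimming:
#' `x = -6.29 - 0.41 BBL + 0.26 HB_COP + 0.10 HA_lat - 0.09 HL_med`,
#' `P = exp(x) / (1 + exp(x))`.
#'
#' @return List with `intercept` and named `coefficients`.
#' @export
frog_risk_model <- function() {
  list(intercept = -6.29,
       coefficients = c(BBL = -0.41, HB_COP = 0.26,
                        HA_lat = 0.10, HL_med = -0.09))
}

#' Predicted probability of increased frog pressure
#'
#' Evaluates `P = exp(x)/(1 + exp(x))` with
#' `x = intercept + sum(coefficients * values)`.
#'
#' @param model A `hoof_logit`, or a list with `intercept` and named
#'   `coefficients` (e.g. [frog_risk_model()]).
#' @param newdata Data frame / named list with one column per model
#'   variable (percentage differences).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
#' @examples
#' predict_probability(frog_risk_model(),
#'                     list(BBL = 0, HB_COP = 0, HA_lat = 0, HL_med = 0))
predict_probability <- function(model, newdata) {
  if (inherits(model, "hoof_logit")) {
    cf <- coef(model$fit)
    intercept <- cf[["(Intercept)"]]
    coefs <- cf[setdiff(names(cf), "(Intercept)")]
    names(coefs) <- gsub("`", "", names(coefs))
  } else {
    intercept <- model$intercept
    coefs <- model$coefficients
  }
  newdata <- as_tibble(lapply(as.list(newdata), as.numeric))
  missing_v <- setdiff(names(coefs), names(newdata))
  if (length(missing_v)) {
    stop_hoofpspm(paste0("missing variable(s): ",
                         paste(missing_v, collapse = ", ")),
                  "hoofpspm_input_contract")
  }
  x <- intercept + as.vector(
    as.matrix(newdata[, names(coefs), drop = FALSE]) %*% coefs)
  plogis(x)
}

#' @export
print.hoof_logit <- function(x, ...) {
  cat(sprintf("<hoof_logit> %d obs (%d events), logLik %.2f\n",
              x$n, x$n_events, x$logLik))
  print(x$coefficients, ...)
  if (nrow(x$trace)) {
    cat("selection trace:\n"); print(x$trace, ...)
  }
  invisible(x)
}

#' Broom-style tidiers for fitted frog-pressure models
#'
#' `tidy()` returns the per-term coefficient table with odds ratios and 95%
#' Wald intervals; `glance()` returns one-row model-level summaries.
#'
#' @param x A `hoof_logit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy hoof_logit
#' @export
tidy.hoof_logit <- function(x, ...) x$coefficients

#' @rdname tidy.hoof_logit
#' @method glance hoof_logit
#' @export
glance.hoof_logit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, logLik = x$logLik,
         AIC = stats::AIC(x$fit), deviance = stats::deviance(x$fit),
         df.residual = stats::df.residual(x$fit),
         n_selected = length(x$variables))
}
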