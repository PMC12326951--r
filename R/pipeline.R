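# End-to-end orchestration: simulate (or accept) a study, run the
# topographic arm per foot, derive outcomes, run the measurement arm, and
# assemble a report bundle.

#' Pipeline configuration
#'
#' Validated settings for [run_pipeline()].  Validation happens here, before
#' any computation: invalid thresholds (e.g. `n_perm = 0`) fail immediately.
#'
#' @param seed Integer seed controlling every stochastic stage.
#' @param n_feet Number of feet in the simulated study.
#' @param alpha Cluster-level significance threshold.
#' @param n_perm Permutations per foot (>= 100).
#' @param cluster_alpha Pixel-level alpha for the cluster-forming threshold.
#' @param mask_prop Analysis-mask support rule (fraction of strikes).
#' @param connectivity Cluster connectivity; only 4 (edge-adjacent) is
#'   supported.
#' @param p_enter,p_remove Forward-LR selection thresholds.
#' @param pool_alpha Univariable p-value below which a measure enters the
#'   candidate pool (default 0.2).
#' @param bonferroni_m Number of tests in the Bonferroni correction.
#' @param cutoff Probability cut-off for sensitivity/specificity.
#' @param print_config A [print_config()] for the synthetic print arm.
#' @param template A [make_region_template()] (left foot).
#' @param outdir Optional output directory for CSV/figure artefacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_feet = 94L, alpha = 0.05,
                            n_perm = 199L, cluster_alpha = 0.05,
                            mask_prop = 0.5, connectivity = 4L,
                            p_enter = 0.05, p_remove = 0.10,
                            pool_alpha = 0.2, bonferroni_m = 18L,
                            cutoff = 0.5,
                            print_config = hoofpspm::print_config(seed = seed),
                            template = make_region_template(),
                            outdir = NULL) {
  check_number(alpha, "alpha", 0, 1, TRUE, TRUE)
  check_number(cluster_alpha, "cluster_alpha", 0, 1, TRUE, TRUE)
  check_number(mask_prop, "mask_prop", 0, 1)
  check_number(p_enter, "p_enter", 0, 1, TRUE, TRUE)
  check_number(p_remove, "p_remove", 0, 1, TRUE, FALSE)
  check_number(pool_alpha, "pool_alpha", 0, 1, TRUE, FALSE)
  check_number(cutoff, "cutoff", 0, 1, TRUE, TRUE)
  if (!identical(as.integer(connectivity), 4L)) {
    stop_hoofpspm("only 4-neighbour connectivity is supported.",
                  "hoofpspm_invalid_config")
  }
  if (!is.numeric(n_perm) || n_perm < 100L) {
    stop_hoofpspm("`n_perm` must be at least 100.", "hoofpspm_invalid_config")
  }
  if (n_feet < 1L) {
    stop_hoofpspm("`n_feet` must be positive.", "hoofpspm_invalid_config")
  }
  structure(
    list(seed = as.integer(seed), n_feet = as.integer(n_feet), alpha = alpha,
         n_perm = as.integer(n_perm), cluster_alpha = cluster_alpha,
         mask_prop = mask_prop, connectivity = 4L, p_enter = p_enter,
         p_remove = p_remove, pool_alpha = pool_alpha,
         bonferroni_m = as.integer(bonferroni_m), cutoff = cutoff,
         print_config = print_config, template = template, outdir = outdir),
    class = "pipeline_config")
}

#' Save / load a pipeline configuration as YAML
#'
#' Scalar settings round-trip through a structured text file; the template
#' is rebuilt from its stored parameters.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  scal <- config[setdiff(names(config), c("print_config", "template"))]
  scal$print_config <- unclass(config$print_config)
  scal$template <- list(dims = config$template$dims,
                        pitch = config$template$pitch,
                        shape = config$template$shape)
  yaml::write_yaml(scal, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pc <- do.call(print_config, y$print_config)
  tpl <- make_region_template(dims = unlist(y$template$dims),
                              pitch = y$template$pitch,
                              shape = y$template$shape)
  args <- y[setdiff(names(y), c("print_config", "template"))]
  args$outdir <- if (is.null(args$outdir)) NULL else args$outdir
  do.call(pipeline_config,
          c(args, list(print_config = pc, template = tpl)))
}

#' Analyse one foot's strikes topographically
#'
#' Convenience wrapper running the whole per-foot chain: validity filtering,
#' mirroring, shared-reference registration, the pixel t-field, cluster
#' permutation inference and region classification.
#'
#' @param strikes List of `peak_print`s for one foot (both conditions).
#' @param template Left-foot `region_template` in the registered frame.
#' @param alpha,n_perm,cluster_alpha,mask_prop As in [pipeline_config()].
#' @param seed Integer seed for the permutation draw.
#' @return List with `stacks`, `t_field`, `clusters` and `outcome`; or, for
#'   feet with too few valid strikes, a list with `excluded = TRUE` and the
#'   valid-strike counts.
#' @export
analyse_foot <- function(strikes, template, alpha = 0.05, n_perm = 199L,
                         cluster_alpha = 0.05, mask_prop = 0.5, seed = 1L) {
  stacks <- tryCatch(
    build_condition_stacks(strikes),
    hoofpspm_foot_excluded = function(e) e)
  if (inherits(stacks, "hoofpspm_foot_excluded")) {
    return(list(excluded = TRUE, n_before = stacks$n_before,
                n_after = stacks$n_after, reason = conditionMessage(stacks)))
  }
  tf <- compute_t_field(stacks$before, stacks$after, mask_prop = mask_prop)
  cr <- cluster_inference(tf, stacks$before, stacks$after, alpha = alpha,
                          n_perm = n_perm, seed = seed,
                          cluster_alpha = cluster_alpha)
  tf_tpl <- tryCatch(align_template_to_stack(template, stacks$stack),
                     error = function(e) NULL)
  out <- classify_outcome(cr, template, alpha = alpha,
                          template_transform = tf_tpl)
  list(excluded = FALSE, stacks = stacks, t_field = tf, clusters = cr,
       outcome = out)
}

#' Run the full two-arm trimming analysis on synthetic data
#'
#' Simulates a pressure-print study, classifies every foot's topographic
#' pressure-change outcome, generates the matching hoof-measurement table,
#' and runs the measurement arm (percentage differences, univariable screen
#' with Bonferroni correction, correlation pruning, forward-LR logistic
#' selection, evaluation).  All randomness derives from `config$seed`;
#' rerunning a config reproduces the bundle exactly.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `report_bundle`: `outcomes` (per-foot tibble),
#'   `summary` (tibble of proportion summaries with formatted text),
#'   `cluster_table`, `screen`, `correlation`, `model`, `evaluation`,
#'   `example_foot` (t-field + clusters of one increase-frog foot for
#'   figures), `figures` (named list of ggplots), `config` and
#'   `config_hash`.  When `config$outdir` is set, CSV artefacts stamped
#'   with the config hash and seed are written there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  study <- simulate_print_study(
    n_feet = config$n_feet, template = config$template,
    config = config$print_config, seed = config$seed)

  foot_seeds <- derive_seeds(config$seed + 2L, nrow(study))
  analyses <- vector("list", nrow(study))
  rows <- vector("list", nrow(study))
  for (i in seq_len(nrow(study))) {
    an <- analyse_foot(study$strikes[[i]], config$template,
                       alpha = config$alpha, n_perm = config$n_perm,
                       cluster_alpha = config$cluster_alpha,
                       mask_prop = config$mask_prop, seed = foot_seeds[i])
    analyses[[i]] <- an
    rows[[i]] <- if (isTRUE(an$excluded)) {
      tibble(foot_id = study$foot_id[i], side = study$side[i],
             is_effect = study$is_effect[i], excluded = TRUE,
             category = NA_character_, n_sig_clusters = NA_integer_,
             min_cluster_p = NA_real_)
    } else {
      sig <- an$outcome$clusters
      tibble(foot_id = study$foot_id[i], side = study$side[i],
             is_effect = study$is_effect[i], excluded = FALSE,
             category = an$outcome$category,
             n_sig_clusters = nrow(sig),
             min_cluster_p = if (nrow(an$clusters$clusters))
               min(an$clusters$clusters$p_value) else NA_real_)
    }
  }
  outcomes <- bind_rows(rows)

  analysed <- filter(outcomes, !.data$excluded)
  n <- nrow(analysed)
  counts <- list(
    any_change = sum(analysed$category != "no_change"),
    increase_frog = sum(analysed$category == "increase_frog"),
    no_change = sum(analysed$category == "no_change"))
  summary_tbl <- bind_rows(lapply(names(counts), function(nm) {
    k <- counts[[nm]]
    ci <- wald_ci_proportion(k, n)
    tibble(quantity = nm, k = k, n = n, percent = ci$percent,
           lower = ci$lower, upper = ci$upper,
           text = format_proportion_summary(k, n))
  }))

  # measurement arm: outcome = topographic increase_frog classification;
  # measures of outcome-positive feet are shifted per the generator defaults
  outcome_vec <- as.integer(analysed$category == "increase_frog")
  if (sum(outcome_vec == 1L) < 2L || sum(outcome_vec == 0L) < 2L) {
    stop_hoofpspm(
      "measurement arm needs at least two feet in each outcome group.",
      "hoofpspm_insufficient_data")
  }
  records <- simulate_records_for_outcomes(
    analysed$foot_id, outcome_vec, seed = config$seed + 5L)
  measure_table <- simulate_measure_table(records, seed = config$seed + 6L)
  records2 <- percent_diff_records(
    measure_table, outcomes = select(records, "foot_id", "outcome"))

  screen <- univariable_screen(records2, alpha = 0.05,
                               m = config$bonferroni_m)
  prio <- setNames(screen$p_value, screen$measure)
  corr <- correlation_screen(records2, priority = prio)
  pool <- intersect(
    corr$retained,
    screen$measure[!is.na(screen$p_value) &
                     screen$p_value < config$pool_alpha])
  model <- forward_lr_select(records2, pool, p_enter = config$p_enter,
                             p_remove = config$p_remove)
  evaluation <- evaluate_model(model, cutoff = config$cutoff)

  cluster_table <- bind_rows(lapply(seq_along(analyses), function(i) {
    an <- analyses[[i]]
    if (isTRUE(an$excluded) || !nrow(an$clusters$clusters)) return(NULL)
    cl <- tidy(an$clusters)
    cl$foot_id <- study$foot_id[i]
    dplyr::relocate(cl, "foot_id")
  }))

  ex_i <- which(outcomes$category == "increase_frog")[1]
  if (is.na(ex_i)) ex_i <- which(!outcomes$excluded)[1]
  ex <- analyses[[ex_i]]
  figures <- plot_foot_panels(ex$t_field, ex$clusters, alpha = config$alpha)
  figures$roc <- autoplot(evaluation)

  bundle <- structure(
    list(outcomes = outcomes, summary = summary_tbl,
         cluster_table = cluster_table, screen = screen, correlation = corr,
         pool = pool, model = model, evaluation = evaluation,
         records = records2, measure_table = measure_table,
         example_foot = list(foot_id = study$foot_id[ex_i],
                             t_field = ex$t_field, clusters = ex$clusters),
         figures = figures, config = config,
         config_hash = config_hash(config)),
    class = "report_bundle")
  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir)
  bundle
}

# per-foot measurement records conditioned on the topographic outcome:
# outcome-positive feet get the generator's default measure shifts
simulate_records_for_outcomes <- function(foot_ids, outcomes, seed = 1L,
                                          shifts = c(HA_lat = 16,
                                                     HL_med = -10.6,
                                                     HB_COP = 6.1,
                                                     BBL = -2.1,
                                                     DHWL_lat = -5.6,
                                                     FRA_T = -7.2)) {
  n_pos <- sum(outcomes == 1L); n_neg <- sum(outcomes == 0L)
  rec <- simulate_group_cohort(n_pos = max(n_pos, 0L), n_neg = n_neg,
                               shifts = shifts, seed = seed)
  # reattach in original foot order (positives were generated first)
  ord <- c(which(outcomes == 1L), which(outcomes == 0L))
  rec <- rec[order(ord), ]
  rec$foot_id <- foot_ids
  rec
}

#' Render a proportion in the reporting house style
#'
#' `"k/n (p% 95% CI lo; hi)"` with integer percents (one decimal below 1%).
#'
#' @param k,n Successes and trials.
#' @return Character scalar.
#' @export
#' @examples
#' format_proportion_summary(12, 94)
format_proportion_summary <- function(k, n) {
  ci <- wald_ci_proportion(k, n)
  sprintf("%d/%d (%s%% 95%% CI %s; %s)", k, n,
          fmt_pct(ci$percent), fmt_pct(ci$lower), fmt_pct(ci$upper))
}

#' Render the fitted model as a prediction-equation string
#'
#' @param model A `hoof_logit`.
#' @return Character scalar of the form
#'   `x = a + [(b1 x V1) + ...]; P = e^x/(1 + e^x)`.
#' @export
format_equation <- function(model) {
  cf <- model$coefficients
  b0 <- cf$estimate[cf$term == "(Intercept)"]
  terms <- cf[cf$term != "(Intercept)", ]
  rhs <- paste(sprintf("(%.2f x %s)", terms$estimate, terms$term),
               collapse = " + ")
  if (nzchar(rhs)) {
    sprintf("x = %.2f + [%s]; P = e^x/(1 + e^x)", b0, rhs)
  } else {
    sprintf("x = %.2f; P = e^x/(1 + e^x)", b0)
  }
}

config_hash <- function(config) {
  scal <- config[setdiff(names(config), c("template", "outdir"))]
  scal$print_config <- unclass(scal$print_config)
  s <- paste(deparse(scal), collapse = "")
  # small stable polynomial hash; avoids external digest dependencies
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# config_hash: %s seed: %d", bundle$config_hash,
                   bundle$config$seed)
  wcsv <- function(df, name) {
    path <- file.path(outdir, name)
    writeLines(stamp, path)
    suppressWarnings(readr::write_csv(df, path, append = TRUE,
                                      col_names = TRUE))
  }
  wcsv(bundle$outcomes, "foot_outcomes.csv")
  if (!is.null(bundle$cluster_table) && nrow(bundle$cluster_table))
    wcsv(bundle$cluster_table, "clusters.csv")
  wcsv(bundle$summary |> select(-dplyr::any_of("text")) |>
         mutate(text = bundle$summary$text), "proportion_summaries.csv")
  wcsv(bundle$screen, "univariable_screen.csv")
  wcsv(tidy(bundle$model), "model_coefficients.csv")
  writeLines(c(stamp, format_equation(bundle$model)),
             file.path(outdir, "model_equation.txt"))
  wcsv(glance(bundle$evaluation), "model_evaluation.csv")
  wcsv(roc_curve_data(bundle$model), "roc_curve.csv")
  write_pipeline_config(bundle$config, file.path(outdir, "config.yaml"))
  invisible(outdir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat(sprintf("  feet analysed: %d (config %s, seed %d)\n",
              sum(!x$outcomes$excluded), x$config_hash, x$config$seed))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-14s %s\n", x$summary$quantity[i], x$summary$text[i]))
  }
  cat(sprintf("  model: %s\n", format_equation(x$model)))
  cat(sprintf("  AUROC %.2f (%.2f; %.2f); HL p = %.2g\n",
              x$evaluation$auroc$auroc, x$evaluation$auroc$lower,
              x$evaluation$auroc$upper, x$evaluation$hl$p_value))
  invisible(x)
}

#' ROC curve coordinates for export
#'
#' @param model A `hoof_logit`.
#' @return Tibble with `threshold`, `sensitivity`, `specificity` (percent).
#' @export
roc_curve_data <- function(model) {
  roc <- pROC::roc(response = model$fit$y,
                   predictor = stats::fitted(model$fit),
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  tibble(threshold = roc$thresholds,
         sensitivity = 100 * roc$sensitivities,
         specificity = 100 * roc$specificities)
}
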