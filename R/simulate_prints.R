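#' Configuration for the synthetic pressure-print generator
#'
#' Bundles the noise and effect structure used to emulate walkway
#' pressure-mat strikes.  Defaults describe the study conditions the package
#' is built around: 14 strikes per foot per condition, a minority (13%) of
#' feet whose frog pressure rises by a multiplicative factor after trimming,
#' modest strike-to-strike pose noise and multiplicative pressure noise.
#'
#' @param strikes_per_condition Valid strikes per foot per condition (>= 4;
#'   a length-2 vector gives unbalanced before/after counts).
#' @param rot_sd_deg SD of per-strike rotation noise (degrees).
#' @param trans_sd_cm SD of per-strike translation noise per axis (cm).
#' @param pixel_noise_sd SD of per-sensel multiplicative log-normal noise
#'   (fraction; 0.1 means ~10% coefficient of variation).
#' @param region_noise_sd SD of per-strike per-region multiplicative
#'   log-normal noise (fraction), shared by all sensels of a region within
#'   one strike.
#' @param frog_effect Multiplier applied to frog-region pressure in the
#'   after-trimming condition of effect feet (> 0; 1 = no effect).
#' @param effect_fraction Fraction of feet that are effect feet, in \[0, 1\].
#' @param seed Integer seed recorded with the config.
#' @return A list of class `print_config`.
#' @export
print_config <- function(strikes_per_condition = 14L,
                         rot_sd_deg = 3,
                         trans_sd_cm = 0.5,
                         pixel_noise_sd = 0.10,
                         region_noise_sd = 0.05,
                         frog_effect = 1.5,
                         effect_fraction = 0.13,
                         seed = 1L) {
  spc <- as.integer(rep(strikes_per_condition, length.out = 2L))
  if (any(spc < 4L)) {
    stop_hoofpspm("at least four strikes per condition are required.",
                  "hoofpspm_invalid_config")
  }
  check_number(rot_sd_deg, "rot_sd_deg", lower = 0)
  check_number(trans_sd_cm, "trans_sd_cm", lower = 0)
  check_number(pixel_noise_sd, "pixel_noise_sd", lower = 0)
  check_number(region_noise_sd, "region_noise_sd", lower = 0)
  check_number(frog_effect, "frog_effect", lower = 0, strict_lower = TRUE)
  check_number(effect_fraction, "effect_fraction", lower = 0, upper = 1)
  structure(list(strikes_per_condition = spc, rot_sd_deg = rot_sd_deg,
                 trans_sd_cm = trans_sd_cm, pixel_noise_sd = pixel_noise_sd,
                 region_noise_sd = region_noise_sd, frog_effect = frog_effect,
                 effect_fraction = effect_fraction, seed = as.integer(seed)),
            class = "print_config")
}

#' Simulate one foot-strike peak print
#'
#' Draws a peak print from the template's generative model: baseline
#' pressure per region, multiplied by a per-strike log-normal factor per
#' region and an independent log-normal factor per sensel, with the frog
#' region additionally multiplied by `config$frog_effect` when the foot is an
#' effect foot measured after trimming; the print is then rigidly displaced
#' by Gaussian pose noise and resampled onto the mat grid.
#'
#' @param template A [make_region_template()] template.
#' @param config A [print_config()].
#' @param condition `"before"` or `"after"`.
#' @param is_effect_foot Does this foot carry the post-trimming frog effect?
#' @param seed Integer seed (deterministic per strike).
#' @param metadata Optional named list (`horse_id`, `foot_id`, `strike_id`).
#' @return A validated `peak_print`.
#' @export
simulate_strike <- function(template, config, condition = c("before", "after"),
                            is_effect_foot = FALSE, seed = 1L,
                            metadata = list()) {
  stopifnot(inherits(template, "region_template"),
            inherits(config, "print_config"))
  condition <- match.arg(condition)
  withr::with_seed(as.integer(seed), {
    press <- template$baseline
    # per-region multiplicative strike effect (wall / sole / frog share one
    # draw each; quarters, toe and heel belong to the sole draw)
    reg_mult <- exp(rnorm(3, 0, config$region_noise_sd))
    press[template$regions$wall] <- press[template$regions$wall] * reg_mult[1]
    press[template$sole] <- press[template$sole] * reg_mult[2]
    press[template$regions$frog] <- press[template$regions$frog] * reg_mult[3]
    if (is_effect_foot && condition == "after") {
      press[template$regions$frog] <-
        press[template$regions$frog] * config$frog_effect
    }
    if (config$pixel_noise_sd > 0) {
      noise <- exp(rnorm(sum(template$support), 0, config$pixel_noise_sd))
      press[template$support] <- press[template$support] * noise
    }
    theta <- if (config$rot_sd_deg > 0) rnorm(1, 0, config$rot_sd_deg) else 0
    shift <- if (config$trans_sd_cm > 0) {
      rnorm(2, 0, config$trans_sd_cm) / template$pitch
    } else c(0, 0)
    if (theta != 0 || any(shift != 0)) {
      res <- resample_rigid(press, theta, shift[1], shift[2])
      press <- res$pressure
    }
  })
  md <- utils::modifyList(
    list(horse_id = NA_character_, foot_id = NA_character_,
         strike_id = NA_integer_),
    metadata)
  validate_strike(peak_print(
    press, pitch = template$pitch, horse_id = md$horse_id,
    foot_id = md$foot_id, side = template$side, condition = condition,
    strike_id = md$strike_id))
}

#' Simulate all strikes for one foot
#'
#' @inheritParams simulate_strike
#' @param seed Base seed; strike seeds are derived deterministically.
#' @return List of `peak_print`s (before strikes first).
#' @export
simulate_foot_strikes <- function(template, config, is_effect_foot = FALSE,
                                  seed = 1L, metadata = list()) {
  n_b <- config$strikes_per_condition[1]
  n_a <- config$strikes_per_condition[2]
  seeds <- derive_seeds(seed, n_b + n_a)
  c(
    lapply(seq_len(n_b), function(i) {
      simulate_strike(template, config, "before", is_effect_foot,
                      seed = seeds[i],
                      metadata = utils::modifyList(metadata,
                                                   list(strike_id = i)))
    }),
    lapply(seq_len(n_a), function(i) {
      simulate_strike(template, config, "after", is_effect_foot,
                      seed = seeds[n_b + i],
                      metadata = utils::modifyList(metadata,
                                                   list(strike_id = i)))
    })
  )
}

#' Simulate a whole pressure-print study
#'
#' Generates `n_feet` feet (alternating left and right; right feet use the
#' mirrored template so the mirroring path of the processing module is
#' exercised), assigns effect-foot status by the configured fraction, and
#' simulates every strike.
#'
#' @param n_feet Number of fore feet.
#' @param template Left-foot `region_template` (right feet are mirrored).
#' @param config A [print_config()].
#' @param seed Integer seed.
#' @param effect_assignment `"binomial"` (each foot independently an effect
#'   foot with probability `effect_fraction`) or `"fixed"` (exactly
#'   `round(effect_fraction * n_feet)` effect feet, chosen at random).
#' @return A tibble with one row per foot: `foot_id`, `horse_id`, `side`,
#'   `is_effect`, and a list-column `strikes` of `peak_print` lists.
#' @export
simulate_print_study <- function(n_feet = 94L,
                                 template = make_region_template(),
                                 config = print_config(),
                                 seed = config$seed,
                                 effect_assignment = c("fixed", "binomial")) {
  effect_assignment <- match.arg(effect_assignment)
  templ_r <- mirror_template(template)
  n_feet <- as.integer(n_feet)
  eff <- withr::with_seed(as.integer(seed), {
    if (effect_assignment == "binomial") {
      runif(n_feet) < config$effect_fraction
    } else {
      k <- round(config$effect_fraction * n_feet)
      e <- rep(FALSE, n_feet); e[sample.int(n_feet, k)] <- TRUE; e
    }
  })
  seeds <- derive_seeds(seed + 1L, n_feet)
  rows <- lapply(seq_len(n_feet), function(i) {
    side <- if (i %% 2L == 1L) "left" else "right"
    tpl <- if (side == "left") template else templ_r
    foot_id <- sprintf("F%03d", i)
    horse_id <- sprintf("H%03d", (i + 1L) %/% 2L)
    strikes <- simulate_foot_strikes(
      tpl, config, is_effect_foot = eff[i], seed = seeds[i],
      metadata = list(horse_id = horse_id, foot_id = foot_id))
    tibble(foot_id = foot_id, horse_id = horse_id, side = side,
           is_effect = eff[i], strikes = list(strikes))
  })
  bind_rows(rows)
}

# deterministic child seeds below 2^31
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed) %% 2147483586L + 1L,
                   sample.int(2147483000L, n))
}
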