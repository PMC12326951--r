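# inverse of a rigid pose (rotation about the reference centroid):
# rotation negates, translation is -R(-theta) t
inverse_pose <- function(theta, dr, dc) {
  a <- theta * pi / 180
  c(-theta,
    -(cos(a) * dr + sin(a) * dc),
    -(-sin(a) * dr + cos(a) * dc))
}

test_that("identical prints register with the identity transform", {
  p1 <- simulate_strike(tpl_default, config_noiseless(), "before", seed = 1)
  p2 <- p1; p2$strike_id <- 2L
  reg <- register_prints(list(p1, p2))
  tr <- reg$transforms[2, ]
  expect_lt(abs(tr$rotation_deg), 0.2)
  expect_lt(abs(tr$dr), 0.1)
  expect_lt(abs(tr$dc), 0.1)
  expect_gt(tr$overlap, 0.99)
})

test_that("known rigid transforms are recovered on noise-free prints", {
  ref <- simulate_strike(tpl_default, config_noiseless(), "before", seed = 1)
  cases <- list(c(7, 2, -1), c(-12, 4, 3), c(15, -5, 2), c(3, 0.5, -4.5))
  withr::with_seed(55, {
    for (i in 1:6) {
      cases[[length(cases) + 1]] <-
        c(runif(1, -15, 15), runif(1, -5, 5), runif(1, -5, 5))
    }
  })
  for (cs in cases) {
    mv <- resample_rigid(ref$pressure, cs[1], cs[2], cs[3])
    mvp <- peak_print(mv$pressure, pitch = tpl_default$pitch,
                      condition = "before", strike_id = 2L)
    reg <- register_prints(list(ref, mvp))
    tr <- reg$transforms[2, ]
    expected <- inverse_pose(cs[1], cs[2], cs[3])
    expect_lt(abs(tr$rotation_deg - expected[1]), 1)
    expect_lt(sqrt((tr$dr - expected[2])^2 + (tr$dc - expected[3])^2), 0.5)
    expect_gt(tr$overlap, 0.9)
  }
})

test_that("refinement never degrades the initial correlation", {
  cfg <- print_config(seed = 2)   # default pose noise
  st <- simulate_foot_strikes(tpl_default, cfg, seed = 21)
  reg <- register_prints(st[1:8])
  tr <- reg$transforms[-1, ]
  expect_true(all(tr$ncc_final >= tr$ncc_init - 1e-9))
})

test_that("pose-noise stacks register with high overlap ratios", {
  cfg <- print_config(rot_sd_deg = 3, seed = 4)
  st <- simulate_foot_strikes(tpl_default, cfg, seed = 13)
  reg <- register_prints(st)
  expect_gt(mean(reg$transforms$overlap), 0.8)
  expect_true(all(reg$transforms$registered))
})

test_that("registration preserves contact area within resampling tolerance", {
  cfg <- print_config(seed = 6)
  st <- simulate_foot_strikes(tpl_default, cfg, seed = 31)[1:10]
  reg <- register_prints(st)
  orig_area <- vapply(st, function(p) sum(p$pressure > 0), 1L)
  new_area <- vapply(reg$masks, sum, 1L)
  expect_true(all(abs(new_area - orig_area) / orig_area <= 0.10))
})

test_that("condition stacks enforce the four-valid-strike minimum", {
  cfg <- config_noiseless(strikes_per_condition = 4L)
  st <- simulate_foot_strikes(tpl_default, cfg, seed = 3)
  stacks <- build_condition_stacks(st)
  expect_length(stacks$before$prints, 4L)
  expect_length(stacks$after$prints, 4L)

  # dropping one before-strike leaves 3 valid -> the foot is excluded
  expect_error(build_condition_stacks(st[-1]),
               class = "hoofpspm_foot_excluded")
  cnd <- tryCatch(build_condition_stacks(st[-1]),
                  hoofpspm_foot_excluded = function(e) e)
  expect_identical(cnd$n_before, 3L)

  # an invalid strike (clipped) is filtered, not stacked
  bad <- st[[1]]
  bad$pressure[1, 10] <- 50
  bad <- validate_strike(bad)
  stacks2 <- build_condition_stacks(c(list(bad), st))
  expect_length(stacks2$before$prints, 4L)
})

test_that("right-fore prints are mirrored before stacking, left passed through", {
  tpl_r <- mirror_template(tpl_default)
  cfg <- config_noiseless(strikes_per_condition = 4L)
  st_r <- simulate_foot_strikes(tpl_r, cfg, seed = 5)
  expect_identical(st_r[[1]]$side, "right")
  stacks <- build_condition_stacks(st_r)
  # after mirroring, the right-foot baseline matches the left template
  expect_equal(stacks$before$prints[[1]], tpl_default$baseline)
  st_l <- simulate_foot_strikes(tpl_default, cfg, seed = 5)
  stacks_l <- build_condition_stacks(st_l)
  expect_equal(stacks_l$before$prints[[1]], tpl_default$baseline)
})
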