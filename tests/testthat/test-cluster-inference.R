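# independent oracle: exhaustive relabelling with plain-loop t statistics
# and flood-fill clustering, computing max extent-with-peak-tiebreak
oracle_cluster_p <- function(B, A, nr, nc, mask, thr) {
  nb <- nrow(B); na <- nrow(A)
  X <- rbind(B, A)
  stat_of <- function(tv) {
    tmat <- matrix(NA_real_, nr, nc); tmat[mask] <- tv
    best <- 0
    for (sgn in c(1, -1)) {
      supra <- !is.na(tmat) & sgn * tmat > thr
      if (!any(supra)) next
      lab <- flood_components(supra)
      for (l in seq_len(max(lab))) {
        px <- which(lab == l)
        pk <- max(abs(tmat[px]))
        best <- max(best, length(px) + (1 - 1 / (1 + pk)))
      }
    }
    best
  }
  tv_of <- function(idx_after) {
    a <- X[idx_after, , drop = FALSE]
    b <- X[-idx_after, , drop = FALSE]
    sapply(seq_len(ncol(X)), function(j) {
      sp <- ((na - 1) * var(a[, j]) + (nb - 1) * var(b[, j])) / (na + nb - 2)
      if (sp <= 1e-12) return(0)
      (mean(a[, j]) - mean(b[, j])) / sqrt(sp * (1 / na + 1 / nb))
    })
  }
  combos <- utils::combn(nb + na, na)
  stats <- apply(combos, 2, function(ix) stat_of(tv_of(ix)))
  obs <- stat_of(tv_of(nb + seq_len(na)))
  list(max_stats = stats, obs = obs,
       p = sum(stats >= obs - 1e-8) / length(stats))
}

test_that("exhaustive permutation p-values match a brute-force oracle", {
  withr::with_seed(21, {
    B <- matrix(200 + rnorm(4 * 12, 0, 15), 4, 12)
    A <- matrix(200 + rnorm(4 * 12, 0, 15), 4, 12)
    A[, 5] <- A[, 5] + 60   # one shifted pixel
  })
  st <- stacks_from_matrix(B, A, 3, 4)
  tf <- compute_t_field(st$before, st$after)
  cr <- cluster_inference(tf, st$before, st$after, n_perm = 100, seed = 1)
  expect_true(cr$exhaustive)           # C(8,4) = 70 <= 100
  expect_identical(cr$n_perm, 70L)
  orc <- oracle_cluster_p(B, A, 3, 4, tf$mask, cr$threshold)
  expect_gt(nrow(cr$clusters), 0)
  top <- cr$clusters[1, ]
  expect_equal(top$p_value, orc$p, tolerance = 1e-12)
  expect_equal(sort(cr$perm_max), sort(orc$max_stats), tolerance = 1e-9)
})

test_that("sampled and exhaustive modes agree on small instances", {
  withr::with_seed(22, {
    B <- matrix(150 + rnorm(4 * 10, 0, 10), 4, 10)
    A <- matrix(150 + rnorm(4 * 10, 0, 10), 4, 10)
    A[, 3] <- A[, 3] + 40
  })
  st <- stacks_from_matrix(B, A, 2, 5)
  tf <- compute_t_field(st$before, st$after)
  ex <- cluster_inference(tf, st$before, st$after, n_perm = 100, seed = 1)
  sm <- cluster_inference(tf, st$before, st$after, n_perm = 2000, seed = 1)
  expect_true(ex$exhaustive)
  expect_true(sm$exhaustive)    # 2000 >= 70 still enumerates
  expect_equal(ex$clusters$p_value, sm$clusters$p_value)
})

test_that("a dominant observed cluster reaches the permutation p floor", {
  # a block of pixels shifted far beyond the noise: every mixed relabelling
  # inflates the within-group variance and kills its t statistics, so the
  # observed cluster statistic exceeds all sampled permutation maxima
  withr::with_seed(31, {
    B <- matrix(100, 14, 20); A <- matrix(100, 14, 20)
    B[, 5:8] <- B[, 5:8] + rnorm(14 * 4, 0, 1)
    A[, 5:8] <- A[, 5:8] + 100 + rnorm(14 * 4, 0, 1)
  })
  st <- stacks_from_matrix(B, A, 4, 5)
  tf <- compute_t_field(st$before, st$after)
  cr <- cluster_inference(tf, st$before, st$after, n_perm = 999, seed = 2)
  expect_false(cr$exhaustive)
  expect_equal(min(cr$clusters$p_value), 1 / 1000)
  # and every reported p respects the (k+1)/(N+1) form
  expect_true(all(abs(cr$clusters$p_value * 1000 -
                        round(cr$clusters$p_value * 1000)) < 1e-9))
})

test_that("inference contracts reject invalid settings", {
  st <- null_condition_stacks(32)
  tf <- compute_t_field(st$before, st$after)
  expect_error(cluster_inference(tf, st$before, st$after, n_perm = 50),
               class = "hoofpspm_invalid_config")
  expect_error(cluster_inference(tf, st$before, st$after, alpha = 0),
               class = "hoofpspm_invalid_config")
})

test_that("outcome classification follows region plurality with frog ties", {
  tpl <- tpl_default
  frog_px <- which(tpl$regions$frog, arr.ind = TRUE)[1:4, ]
  quarter_px <- which(tpl$regions$medial_quarter, arr.ind = TRUE)[1:3, ]
  lat_px <- which(tpl$regions$lateral_quarter, arr.ind = TRUE)[1:3, ]
  mk_cl <- function(px, sign, p) {
    tibble::tibble(cluster_id = 1L, sign = sign, extent = nrow(px),
                   peak_t = if (sign == "increase") 5 else -5,
                   pixels = list(tibble::tibble(row = px[, 1], col = px[, 2])),
                   p_value = p)
  }
  # significant positive cluster wholly in the frog
  cr <- manual_cluster_result(mk_cl(frog_px, "increase", 0.002))
  expect_identical(classify_outcome(cr, tpl)$category, "increase_frog")
  # significant negative frog cluster
  cr <- manual_cluster_result(mk_cl(frog_px, "decrease", 0.01))
  expect_identical(classify_outcome(cr, tpl)$category, "decrease_frog")
  # significant clusters only in the quarters
  cr <- manual_cluster_result(dplyr::bind_rows(
    mk_cl(quarter_px, "increase", 0.01), mk_cl(lat_px, "increase", 0.02)))
  expect_identical(classify_outcome(cr, tpl)$category, "change_other_region")
  # nothing below alpha
  cr <- manual_cluster_result(mk_cl(frog_px, "increase", 0.2))
  expect_identical(classify_outcome(cr, tpl)$category, "no_change")
  # tie between frog and another region resolves toward the frog
  half <- rbind(frog_px[1:2, ], quarter_px[1:2, ])
  cr <- manual_cluster_result(mk_cl(half, "increase", 0.01))
  out <- classify_outcome(cr, tpl)
  expect_identical(out$clusters$region[1], "frog")
  expect_identical(out$category, "increase_frog")
})

test_that("smoothing the stacks leaves the null p-value distribution valid", {
  smooth3 <- function(m) {
    k <- c(0.25, 0.5, 0.25)
    sh <- function(mm, dr, dc) {
      o <- matrix(0, nrow(mm), ncol(mm))
      rs <- seq_len(nrow(mm)) - dr; cs <- seq_len(ncol(mm)) - dc
      okr <- rs >= 1 & rs <= nrow(mm); okc <- cs >= 1 & cs <= ncol(mm)
      o[okr, okc] <- mm[rs[okr], cs[okc]]
      o
    }
    m2 <- k[2] * m + k[1] * (sh(m, 1, 0) + sh(m, -1, 0))
    k[2] * m2 + k[1] * (sh(m2, 0, 1) + sh(m2, 0, -1))
  }
  ps <- vapply(1:40, function(i) {
    st <- null_condition_stacks(400 + i)
    sm <- function(s) { s$prints <- lapply(s$prints, smooth3); s }
    b <- sm(st$before); a <- sm(st$after)
    tf <- compute_t_field(b, a)
    cr <- cluster_inference(tf, b, a, n_perm = 199, seed = i)
    if (nrow(cr$clusters)) min(cr$clusters$p_value) else 1
  }, numeric(1))
  # familywise: under the null, small p-values stay rare after smoothing
  expect_lte(mean(ps < 0.05), 0.15)
})
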