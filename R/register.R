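# Rigid resampling and print-to-print registration.
#
# Transform convention: a transform (theta, dr, dc) rotates the moving print
# by theta degrees (counter-clockwise in row/col space) about its own support
# centroid and then translates it by (dr, dc) sensels.  Resampling is
# bilinear on pressures (negatives clamped to 0); the binary support mask is
# warped separately and thresholded at 0.5, which preserves contact area.

#' Apply a rigid transform to a pressure image
#'
#' @param mat Numeric pressure matrix (kPa).
#' @param theta Rotation in degrees (counter-clockwise, row/col space).
#' @param dr,dc Translation in sensels (rows, cols).
#' @param centre Rotation centre `c(row, col)`; defaults to the support
#'   centroid of `mat`.
#' @param with_mask Also warp the binary support mask (skippable inside
#'   optimiser loops).
#' @return List with `pressure` (bilinear, clamped at 0) and `mask`
#'   (warped binary support, 0.5-thresholded; `NULL` if skipped).
#' @export
resample_rigid <- function(mat, theta, dr, dc, centre = NULL,
                           with_mask = TRUE) {
  if (is.null(centre)) centre <- support_centroid(mat > 0)
  if (theta == 0 && dr == round(dr) && dc == round(dc)) {
    # pure integer shift: exact, no interpolation blur
    out <- shift_integer(mat, round(dr), round(dc))
    return(list(pressure = out, mask = out > 0))
  }
  nr <- nrow(mat); nc <- ncol(mat)
  th <- theta * pi / 180
  R <- seq_len(nr); C <- seq_len(nc)
  gr <- matrix(R, nr, nc) - (centre[1] + dr)
  gc <- matrix(C, nr, nc, byrow = TRUE) - (centre[2] + dc)
  # inverse rotation of the offset from the (translated) centre
  sr <- centre[1] + cos(th) * gr + sin(th) * gc
  sc <- centre[2] - sin(th) * gr + cos(th) * gc
  if (!with_mask) {
    pres <- bilinear_sample(mat, sr, sc)
    pres[pres < 0] <- 0
    return(list(pressure = matrix(pres, nr, nc), mask = NULL))
  }
  res <- bilinear_sample2(mat, (mat > 0) * 1, sr, sc)
  pres <- res$a
  pres[pres < 0] <- 0
  msk <- res$b >= 0.5
  pres[!msk] <- 0
  list(pressure = matrix(pres, nr, nc), mask = matrix(msk, nr, nc))
}

bilinear_sample <- function(mat, sr, sc) {
  nr <- nrow(mat); nc <- ncol(mat)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  val <- function(r, c) {
    # clamp into range and zero out-of-bounds via a multiplicative flag;
    # flat indexing avoids cbind overhead in the optimiser's inner loop
    ok <- (r >= 1) * (r <= nr) * (c >= 1) * (c <= nc)
    rr <- pmin.int(pmax.int(r, 1), nr)
    cc <- pmin.int(pmax.int(c, 1), nc)
    mat[(cc - 1) * nr + rr] * ok
  }
  v00 <- val(r0, c0); v01 <- val(r0, c0 + 1)
  v10 <- val(r0 + 1, c0); v11 <- val(r0 + 1, c0 + 1)
  (1 - fr) * (1 - fc) * v00 + (1 - fr) * fc * v01 +
    fr * (1 - fc) * v10 + fr * fc * v11
}

# bilinear sampling of two images at the same coordinates with one set of
# index computations (the registration objective's inner loop)
bilinear_sample2 <- function(mat_a, mat_b, sr, sc) {
  nr <- nrow(mat_a); nc <- ncol(mat_a)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  out_a <- 0; out_b <- 0
  for (k in 1:4) {
    dr <- c(0L, 0L, 1L, 1L)[k]; dc <- c(0L, 1L, 0L, 1L)[k]
    r <- r0 + dr; c <- c0 + dc
    ok <- (r >= 1) * (r <= nr) * (c >= 1) * (c <= nc)
    rr <- pmin.int(pmax.int(r, 1), nr)
    cc <- pmin.int(pmax.int(c, 1), nc)
    idx <- (cc - 1) * nr + rr
    w <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc) * ok
    out_a <- out_a + w * mat_a[idx]
    out_b <- out_b + w * mat_b[idx]
  }
  list(a = out_a, b = out_b)
}

shift_integer <- function(mat, dr, dc) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(0, nr, nc)
  src_r <- seq_len(nr) - dr; src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- mat[src_r[ok_r], src_c[ok_c]]
  out
}

support_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

# orientation of the principal axis of a support mask, degrees in (-90, 90]
principal_angle <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  r <- idx[, 1] - mean(idx[, 1]); c <- idx[, 2] - mean(idx[, 2])
  mu20 <- mean(r^2); mu02 <- mean(c^2); mu11 <- mean(r * c)
  0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
}

jaccard_overlap <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

ncc <- function(a, b) {
  sa <- sd(a); sb <- sd(b)
  if (sa == 0 || sb == 0) return(NA_real_)
  cor(as.vector(a), as.vector(b))
}

#' Register peak prints to a common pose
#'
#' Rigidly aligns a set of peak prints to a reference print so that sensels
#' correspond anatomically across strikes.  Each print is initialised by
#' centroid alignment plus principal-axis rotation and refined by maximising
#' the normalised cross-correlation of the pressure images over rotation and
#' translation (Nelder-Mead).  Per-print transforms, Jaccard support-overlap
#' ratios and correlation before/after refinement are recorded; prints whose
#' overlap falls below `overlap_warn` are flagged.
#'
#' @param prints List of valid `peak_print`s sharing pitch and grid dims.
#' @param reference_policy `"first"` (default: first print in the list is the
#'   reference) or an integer index into `prints`.
#' @param overlap_warn Overlap ratio below which a print is flagged
#'   (default 0.8, the level regarded as a usually-attainable registration).
#' @return A `registered_stack`: list with `prints` (aligned pressure
#'   matrices), `masks` (aligned supports), `transforms` (tibble with
#'   `strike_id`, `condition`, `rotation_deg`, `dr`, `dc`, `overlap`,
#'   `ncc_init`, `ncc_final`, `flagged`, `registered`), `reference` index and
#'   `pitch`.
#' @export
register_prints <- function(prints, reference_policy = "first",
                            overlap_warn = 0.8) {
  stopifnot(length(prints) >= 2L,
            all(vapply(prints, inherits, TRUE, "peak_print")))
  pitches <- vapply(prints, `[[`, 1.0, "pitch")
  if (length(unique(pitches)) != 1L) {
    stop_hoofpspm("all prints must share one sensel pitch.",
                  "hoofpspm_format")
  }
  ref_i <- if (identical(reference_policy, "first")) 1L
           else as.integer(reference_policy)
  ref <- prints[[ref_i]]$pressure
  ref_mask <- ref > 0
  ref_cent <- support_centroid(ref_mask)
  ref_ang <- principal_angle(ref_mask)

  n <- length(prints)
  aligned <- vector("list", n); masks <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- prints[[i]]$pressure
    if (i == ref_i) {
      aligned[[i]] <- ref; masks[[i]] <- ref_mask
      rows[[i]] <- tibble(
        strike_id = prints[[i]]$strike_id, condition = prints[[i]]$condition,
        rotation_deg = 0, dr = 0, dc = 0, overlap = 1,
        ncc_init = 1, ncc_final = 1, flagged = FALSE, registered = TRUE)
      next
    }
    fit <- register_one(p, ref, ref_cent, ref_ang)
    if (is.null(fit)) {
      aligned[[i]] <- NULL; masks[[i]] <- NULL
      rows[[i]] <- tibble(
        strike_id = prints[[i]]$strike_id, condition = prints[[i]]$condition,
        rotation_deg = NA_real_, dr = NA_real_, dc = NA_real_,
        overlap = NA_real_, ncc_init = NA_real_, ncc_final = NA_real_,
        flagged = TRUE, registered = FALSE)
      warn(sprintf("print %s could not be registered and was excluded.",
                   prints[[i]]$strike_id), class = "hoofpspm_unregistrable")
      next
    }
    ov <- jaccard_overlap(fit$mask, ref_mask)
    aligned[[i]] <- fit$pressure; masks[[i]] <- fit$mask
    rows[[i]] <- tibble(
      strike_id = prints[[i]]$strike_id, condition = prints[[i]]$condition,
      rotation_deg = fit$par[1], dr = fit$par[2], dc = fit$par[3],
      overlap = ov, ncc_init = fit$ncc_init, ncc_final = fit$ncc_final,
      flagged = ov < overlap_warn, registered = TRUE)
  }
  keep <- !vapply(aligned, is.null, TRUE)
  structure(
    list(prints = aligned[keep], masks = masks[keep],
         transforms = bind_rows(rows),
         reference = ref_i, pitch = pitches[1],
         meta = tibble(
           strike_id = vapply(prints, `[[`, NA_integer_, "strike_id")[keep],
           condition = vapply(prints, `[[`, NA_character_, "condition")[keep])),
    class = "registered_stack"
  )
}

# Register one moving print to the reference; returns NULL on failure.
#
# The fit uses the backward formulation: the candidate transform G (rotation
# theta_g about the reference support centroid, then translation t_g) is
# applied to the REFERENCE, and NCC is taken against the untouched moving
# print.  When the moving print is (a resampling of) a rigidly displaced
# reference, the objective is exactly 1 at the true pose, so the estimator
# carries no interpolation bias.  The reported transform is the inverse of
# the fitted G: it maps the moving print back onto the reference frame
# (rotation about the reference centroid).
register_one <- function(moving, ref, ref_cent, ref_ang) {
  mov_mask <- moving > 0
  if (!any(mov_mask) || sd(as.vector(ref)) == 0 ||
      sd(as.vector(moving)) == 0) return(NULL)
  mov_cent <- support_centroid(mov_mask)
  th0 <- principal_angle(mov_mask) - ref_ang
  if (th0 > 90) th0 <- th0 - 180
  if (th0 < -90) th0 <- th0 + 180
  par0 <- c(th0, mov_cent[1] - ref_cent[1], mov_cent[2] - ref_cent[2])
  obj <- function(par) {
    # full path (incl. mask zeroing) so the objective matches the output of
    # resample_rigid exactly; at the true pose of a warped print NCC is 1
    res <- resample_rigid(ref, par[1], par[2], par[3], centre = ref_cent)
    v <- ncc(res$pressure, moving)
    if (is.na(v)) 1 else -v
  }
  f0 <- obj(par0)
  if (!is.finite(f0)) return(NULL)
  # coarse rotation scan around the principal-axis estimate guards against
  # local optima when the axis angle is poorly determined
  scan <- vapply(seq(-9, 9, by = 3),
                 function(d) obj(par0 + c(d, 0, 0)), numeric(1))
  par0[1] <- par0[1] + seq(-9, 9, by = 3)[which.min(scan)]
  opt <- tryCatch(
    optim(par0, obj, method = "Nelder-Mead",
          control = list(reltol = 1e-7, maxit = 170)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value)) return(NULL)
  # Nelder-Mead restart from the found optimum polishes the simplex
  opt2 <- tryCatch(
    optim(opt$par, obj, method = "Nelder-Mead",
          control = list(reltol = 1e-8, maxit = 120)),
    error = function(e) NULL)
  if (!is.null(opt2) && is.finite(opt2$value) && opt2$value <= opt$value)
    opt <- opt2
  # invert G: rotate by -theta_g about the reference centroid, translate by
  # -R(-theta_g) t_g
  th <- -opt$par[1]
  a <- opt$par[1] * pi / 180
  tg <- opt$par[2:3]
  tt <- -c(cos(a) * tg[1] + sin(a) * tg[2],
           -sin(a) * tg[1] + cos(a) * tg[2])
  res <- resample_rigid(moving, th, tt[1], tt[2], centre = ref_cent)
  list(pressure = res$pressure, mask = res$mask, par = c(th, tt),
       ncc_init = -f0, ncc_final = -opt$value)
}

#' Assemble a registered stack from already-aligned prints
#'
#' For prints that are known to share one pose (e.g. simulated with zero
#' pose noise, or externally registered) this skips the optimisation and
#' records identity transforms.
#'
#' @param prints List of `peak_print`s on one grid.
#' @return A `registered_stack` with identity transforms.
#' @export
stack_from_prints <- function(prints) {
  stopifnot(length(prints) >= 2L,
            all(vapply(prints, inherits, TRUE, "peak_print")))
  ref_mask <- prints[[1]]$pressure > 0
  masks <- lapply(prints, function(p) p$pressure > 0)
  structure(
    list(prints = lapply(prints, `[[`, "pressure"), masks = masks,
         transforms = tibble(
           strike_id = vapply(prints, `[[`, NA_integer_, "strike_id"),
           condition = vapply(prints, `[[`, NA_character_, "condition"),
           rotation_deg = 0, dr = 0, dc = 0,
           overlap = vapply(masks, jaccard_overlap, 1.0, ref_mask),
           ncc_init = NA_real_, ncc_final = NA_real_,
           flagged = FALSE, registered = TRUE),
         reference = 1L, pitch = prints[[1]]$pitch,
         meta = tibble(
           strike_id = vapply(prints, `[[`, NA_integer_, "strike_id"),
           condition = vapply(prints, `[[`, NA_character_, "condition"))),
    class = "registered_stack")
}

#' @export
print.registered_stack <- function(x, ...) {
  cat(sprintf("<registered_stack> %d aligned prints (reference #%d)\n",
              length(x$prints), x$reference))
  ov <- x$transforms$overlap
  cat(sprintf("  overlap ratio: mean %.3f, min %.3f; %d flagged\n",
              mean(ov, na.rm = TRUE), min(ov, na.rm = TRUE),
              sum(x$transforms$flagged, na.rm = TRUE)))
  invisible(x)
}

#' Build registered before/after stacks for one foot
#'
#' Filters invalid strikes, mirrors right-fore prints into the left-foot
#' frame, checks the minimum of four valid strikes per condition, and
#' registers every strike of both conditions to a single shared reference
#' (the first valid before-trimming strike) so that pixels correspond across
#' conditions.
#'
#' @param prints List of `peak_print`s for one foot, both conditions,
#'   validity flags set (unset flags are computed here).
#' @param min_strikes Minimum valid strikes required per condition.
#' @param overlap_warn Passed to [register_prints()].
#' @return List with elements `before` and `after` (each a
#'   `registered_stack` restricted to that condition), `stack` (the joint
#'   stack), and `n_valid` (named counts).  Feet with fewer than
#'   `min_strikes` valid strikes in either condition raise a classed
#'   `hoofpspm_foot_excluded` error carrying the counts.
#' @export
build_condition_stacks <- function(prints, min_strikes = 4L,
                                   overlap_warn = 0.8) {
  prints <- lapply(prints, function(p) {
    if (is.na(p$valid)) validate_strike(p) else p
  })
  prints <- lapply(prints, function(p) {
    if (identical(p$side, "right") && !isTRUE(p$mirrored)) mirror_print(p)
    else p
  })
  valid <- keep(prints, ~ isTRUE(.x$valid))
  cond <- vapply(valid, `[[`, NA_character_, "condition")
  n_before <- sum(cond == "before"); n_after <- sum(cond == "after")
  if (n_before < min_strikes || n_after < min_strikes) {
    stop_hoofpspm(
      sprintf("foot excluded: %d valid before / %d valid after strikes (need >= %d).",
              n_before, n_after, min_strikes),
      "hoofpspm_foot_excluded",
      n_before = n_before, n_after = n_after, min_strikes = min_strikes)
  }
  ord <- order(match(cond, c("before", "after")))
  valid <- valid[ord]
  stack <- register_prints(valid, reference_policy = "first",
                           overlap_warn = overlap_warn)
  subset_stack <- function(s, condition) {
    sel <- s$meta$condition == condition
    s2 <- s
    s2$prints <- s$prints[sel]; s2$masks <- s$masks[sel]
    s2$meta <- s$meta[sel, ]
    s2$transforms <- s$transforms[s$transforms$condition == condition, ]
    s2
  }
  list(before = subset_stack(stack, "before"),
       after = subset_stack(stack, "after"),
       stack = stack,
       n_valid = c(before = n_before, after = n_after))
}
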