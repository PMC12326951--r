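#' Pixel-level two-sample t-field between conditions
#'
#' Computes, at every analysed sensel, the pooled-variance two-sample
#' t-statistic comparing after-trimming against before-trimming peak
#' pressures across strikes.  Positive t means higher pressure after
#' trimming.  The analysis mask keeps sensels present in the support of at
#' least `mask_prop` of all strikes (both conditions pooled); sensels with
#' zero pooled variance are masked out.
#'
#' @param before_stack,after_stack `registered_stack`s on one common grid
#'   (built by [build_condition_stacks()] so pixels correspond).
#' @param mask_prop Minimum fraction of strikes whose support must contain a
#'   sensel for it to be tested (default 0.5).
#' @return An object of class `t_field`: list with `t` (matrix, `NA` off
#'   mask), `df` (n1 + n2 - 2), `mask` (logical matrix), `n_before`,
#'   `n_after`, and the mean pressure images `mean_before`, `mean_after`.
#' @export
compute_t_field <- function(before_stack, after_stack, mask_prop = 0.5) {
  stopifnot(inherits(before_stack, "registered_stack"),
            inherits(after_stack, "registered_stack"))
  db <- dim(before_stack$prints[[1]]); da <- dim(after_stack$prints[[1]])
  if (!identical(db, da)) {
    stop_hoofpspm("stacks are not on a common grid; register them together.",
                  "hoofpspm_registration_contract")
  }
  nb <- length(before_stack$prints); na <- length(after_stack$prints)
  if (nb < 2L || na < 2L) {
    stop_hoofpspm("need at least two strikes per condition.",
                  "hoofpspm_insufficient_data")
  }
  B <- t(vapply(before_stack$prints, as.vector, numeric(prod(db))))
  A <- t(vapply(after_stack$prints, as.vector, numeric(prod(db))))
  supp <- t(vapply(c(before_stack$masks, after_stack$masks),
                   as.vector, logical(prod(db))))
  mask_v <- colMeans(supp) >= mask_prop
  mb <- colMeans(B); ma <- colMeans(A)
  ssb <- colSums(B^2) - nb * mb^2
  ssa <- colSums(A^2) - na * ma^2
  df <- nb + na - 2L
  vp <- (ssb + ssa) / df
  mask_v <- mask_v & vp > 1e-12
  tv <- rep(NA_real_, length(mask_v))
  tv[mask_v] <- (ma[mask_v] - mb[mask_v]) /
    sqrt(vp[mask_v] * (1 / nb + 1 / na))
  structure(
    list(t = matrix(tv, db[1], db[2]), df = df,
         mask = matrix(mask_v, db[1], db[2]),
         n_before = nb, n_after = na,
         mean_before = matrix(mb, db[1], db[2]),
         mean_after = matrix(ma, db[1], db[2])),
    class = "t_field"
  )
}

#' @export
print.t_field <- function(x, ...) {
  cat(sprintf("<t_field> %d x %d grid, %d sensels tested, df = %d (n = %d + %d)\n",
              nrow(x$t), ncol(x$t), sum(x$mask), x$df, x$n_before, x$n_after))
  cat(sprintf("  t range on mask: [%.2f, %.2f]\n",
              min(x$t, na.rm = TRUE), max(x$t, na.rm = TRUE)))
  invisible(x)
}

#' @rdname tidy_prints
#' @method tidy t_field
#' @export
tidy.t_field <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  tibble(row = as.integer(idx[, 1]), col = as.integer(idx[, 2]),
         t = x$t[idx],
         mean_before_kpa = x$mean_before[idx],
         mean_after_kpa = x$mean_after[idx])
}
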