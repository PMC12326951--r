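# Cluster-level permutation inference on t-fields and anatomical labelling
# of significant clusters.

#' Cluster-level significance by permutation of condition labels
#'
#' Forms clusters of sensels whose |t| exceeds the cluster-forming threshold
#' (two-tailed critical t at `cluster_alpha`, 4-neighbour connectivity,
#' positive and negative excursions clustered separately) and assigns each
#' cluster a familywise-corrected p-value from the permutation distribution
#' of the maximum supra-threshold cluster extent under random relabelling of
#' strikes between the before and after conditions.  When the total number
#' of distinct relabellings is at most `n_perm` the permutation distribution
#' is enumerated exhaustively; otherwise `n_perm` random relabellings are
#' drawn and the p-value uses the standard (k+1)/(N+1) estimator.
#'
#' Cluster extents on a coarse sensel grid are small integers, so the raw
#' extent statistic ties heavily and the test becomes conservative.  Ties
#' are therefore broken by cluster peak |t|: the ordering statistic is
#' `extent + (1 - 1/(1 + peak|t|))`, which sorts primarily by extent and
#' within equal extents by peak height, restoring near-nominal familywise
#' error without changing which clusters are larger than which.
#'
#' @param t_field A [compute_t_field()] result for the observed labelling.
#' @param before_stack,after_stack The stacks the t-field was computed from.
#' @param alpha Cluster-level significance threshold (stored for reporting).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the sampled-permutation mode.
#' @param cluster_alpha Two-tailed pixel-level alpha defining the
#'   cluster-forming threshold (default 0.05).
#' @return An object of class `cluster_result`: tibble `clusters`
#'   (`cluster_id`, `sign`, `extent`, `peak_t`, `p_value`, `pixels`
#'   list-column of row/col tibbles), plus `threshold`, `df`, `n_perm`,
#'   `exhaustive`, `alpha`, `seed` and the `perm_max` null distribution.
#' @export
cluster_inference <- function(t_field, before_stack, after_stack,
                              alpha = 0.05, n_perm = 999L, seed = 1L,
                              cluster_alpha = 0.05) {
  stopifnot(inherits(t_field, "t_field"))
  check_number(alpha, "alpha", 0, 1, TRUE, TRUE)
  if (n_perm < 100L) {
    stop_hoofpspm("`n_perm` must be at least 100.", "hoofpspm_invalid_config")
  }
  nb <- t_field$n_before; na <- t_field$n_after
  if (nb < 2L || na < 2L) {
    stop_hoofpspm("need at least two strikes per condition.",
                  "hoofpspm_insufficient_data")
  }
  thr <- qt(1 - cluster_alpha / 2, df = t_field$df)

  obs <- find_clusters(t_field$t, thr)

  # masked pixel values per strike, before rows then after rows
  mask <- t_field$mask
  X <- rbind(
    t(vapply(before_stack$prints, function(m) m[mask], numeric(sum(mask)))),
    t(vapply(after_stack$prints, function(m) m[mask], numeric(sum(mask)))))
  n <- nb + na
  total <- choose(n, na)
  exhaustive <- total <= n_perm
  if (exhaustive) {
    combos <- combn(n, na)
    L <- matrix(0, ncol(combos), n)
    L[cbind(rep(seq_len(ncol(combos)), each = na), as.vector(combos))] <- 1
  } else {
    L <- withr::with_seed(as.integer(seed), {
      t(replicate(n_perm, {
        v <- numeric(n); v[sample.int(n, na)] <- 1; v
      }))
    })
  }
  perm_max <- perm_max_stats(X, L, na, nb, thr, mask)

  clusters <- obs
  if (nrow(clusters)) {
    obs_stat <- lex_stat(clusters$extent, clusters$peak_t)
    # tolerance guards the exact tie between the observed statistic and the
    # identity relabelling, which travels a different floating-point path
    clusters$p_value <- vapply(obs_stat, function(s) {
      k <- sum(perm_max >= s - 1e-8)
      if (exhaustive) k / length(perm_max)
      else (1 + k) / (length(perm_max) + 1)
    }, numeric(1))
  } else {
    clusters$p_value <- numeric(0)
  }
  structure(
    list(clusters = clusters, threshold = thr, df = t_field$df,
         n_perm = nrow(L), exhaustive = exhaustive, alpha = alpha,
         seed = as.integer(seed), perm_max = perm_max),
    class = "cluster_result"
  )
}

# observed clusters of a t matrix at threshold thr (per sign, 4-neighbour)
find_clusters <- function(tmat, thr) {
  rows <- list()
  for (sgn in c(1, -1)) {
    supra <- !is.na(tmat) & (sgn * tmat > thr)
    if (!any(supra)) next
    comp <- label_components4(supra)
    for (l in seq_len(comp$n)) {
      sel <- comp$label == l
      px <- tibble(row = comp$row[sel], col = comp$col[sel])
      tv <- tmat[cbind(px$row, px$col)]
      rows[[length(rows) + 1L]] <- tibble(
        sign = if (sgn > 0) "increase" else "decrease",
        extent = sum(sel), peak_t = tv[which.max(abs(tv))],
        pixels = list(px))
    }
  }
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(sign = character(), extent = integer(),
                  peak_t = numeric(), pixels = list())
  }
  out <- arrange(out, dplyr::desc(.data$extent))
  out$cluster_id <- seq_len(nrow(out))
  dplyr::relocate(out, "cluster_id")
}

# extent-with-peak-tiebreak ordering statistic: integer part is the extent,
# fractional part breaks ties by peak |t|
lex_stat <- function(extent, peak_t) {
  pk <- abs(peak_t)
  frac <- ifelse(is.finite(pk), 1 - 1 / (1 + pk), 1)
  extent + frac
}

# maximum supra-threshold cluster statistic for each relabelling row of L
perm_max_stats <- function(X, L, na, nb, thr, mask) {
  n <- na + nb
  S <- colSums(X); Q <- colSums(X^2)
  S1 <- L %*% X; Q1 <- L %*% X^2
  m1 <- S1 / na; m0 <- (rep(1, nrow(L)) %o% S - S1) / nb
  ss1 <- Q1 - na * m1^2
  ss0 <- (rep(1, nrow(L)) %o% Q - Q1) - nb * m0^2
  df <- n - 2L
  vp <- (ss1 + ss0) / df
  se <- sqrt(vp * (1 / na + 1 / nb))
  tmatp <- (m1 - m0) / se
  tmatp[se == 0] <- 0          # within-group constant and equal means
  tmatp[se == 0 & abs(m1 - m0) > 1e-12] <- Inf
  nr <- nrow(mask)
  grid <- matrix(FALSE, nr, ncol(mask))
  mask_ids <- which(mask)
  vapply(seq_len(nrow(L)), function(b) {
    tv <- tmatp[b, ]
    mx <- 0
    for (sgn in c(1, -1)) {
      supra <- sgn * tv > thr
      if (!any(supra)) next
      g <- grid
      g[mask_ids[supra]] <- TRUE
      mx <- max(mx, max_cluster_stat(g, mask_ids[supra], tv[supra]))
    }
    mx
  }, numeric(1))
}

# largest lex_stat over 4-connected components of a logical matrix
max_cluster_stat <- function(supra, supra_ids, tv_supra) {
  idx <- which(supra, arr.ind = TRUE)
  sub <- supra[min(idx[, 1]):max(idx[, 1]),
               min(idx[, 2]):max(idx[, 2]), drop = FALSE]
  comp <- label_components4(sub)
  # map component labels back to the t values (ordering of which() is
  # column-major and preserved by the crop offsets)
  ord <- order(supra_ids)       # which(supra) is already sorted; keep safe
  tv_by_pix <- abs(tv_supra[ord])
  ext <- tabulate(comp$label)
  pk <- vapply(seq_len(comp$n), function(l) max(tv_by_pix[comp$label == l]),
               numeric(1))
  max(lex_stat(ext, pk))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> %d cluster(s) at |t| > %.2f (df = %d), %s%d permutations\n",
    nrow(x$clusters), x$threshold, x$df,
    if (x$exhaustive) "exhaustive " else "", x$n_perm))
  if (nrow(x$clusters)) {
    print(select(x$clusters, -"pixels"), ...)
  }
  invisible(x)
}

#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) {
  select(x$clusters, -"pixels")
}

#' Classify a foot's pressure-change outcome by solar region
#'
#' Maps each significant cluster to the template region containing the
#' plurality of its pixels (frog wins ties when its share equals the
#' maximum) and classifies the foot: `increase_frog` if any significant
#' positive cluster maps to the frog, else `decrease_frog` if any
#' significant negative cluster maps to the frog, else
#' `change_other_region` if any significant cluster exists, else
#' `no_change`.
#'
#' @param cluster_result A [cluster_inference()] result.
#' @param template The [make_region_template()] the foot was generated from
#'   or measured against (same side/orientation as the registered stack).
#' @param alpha Cluster-level significance threshold.
#' @param template_transform Optional rigid transform `list(theta, dr, dc)`
#'   mapping the template onto the registered reference frame (see
#'   [align_template_to_stack()]); `NULL` = template already in frame.
#' @return An object of class `foot_outcome`: list with `category`,
#'   `clusters` (tibble with `region` and per-region overlap fractions) and
#'   `alpha`.
#' @export
classify_outcome <- function(cluster_result, template, alpha = 0.05,
                             template_transform = NULL) {
  if (!inherits(template, "region_template")) {
    stop_hoofpspm("a region template is required for classification.",
                  "hoofpspm_invalid_config")
  }
  regions <- template$regions
  if (!is.null(template_transform)) {
    tf <- template_transform
    regions <- lapply(regions, function(m) {
      resample_rigid((m) * 1, tf$theta, tf$dr, tf$dc,
                     centre = support_centroid(template$support))$mask
    })
  }
  cl <- cluster_result$clusters
  sig <- cl[cl$p_value < alpha, , drop = FALSE]
  if (nrow(sig)) {
    lab <- character(nrow(sig)); fracs <- vector("list", nrow(sig))
    for (i in seq_len(nrow(sig))) {
      px <- sig$pixels[[i]]
      share <- vapply(regions, function(m) {
        mean(m[cbind(px$row, px$col)])
      }, numeric(1))
      fracs[[i]] <- share
      mx <- max(share)
      lab[i] <- if (mx == 0) "outside"
        else if (share[["frog"]] == mx) "frog"   # frog-favouring tie-break
        else names(share)[which.max(share)]
    }
    sig$region <- lab
    sig$region_fractions <- fracs
  } else {
    sig$region <- character(0)
    sig$region_fractions <- list()
  }
  category <- if (any(sig$region == "frog" & sig$sign == "increase")) {
    "increase_frog"
  } else if (any(sig$region == "frog" & sig$sign == "decrease")) {
    "decrease_frog"
  } else if (nrow(sig) > 0) {
    "change_other_region"
  } else "no_change"
  structure(list(category = category, clusters = sig, alpha = alpha),
            class = "foot_outcome")
}

#' @export
print.foot_outcome <- function(x, ...) {
  cat(sprintf("<foot_outcome> %s (%d significant cluster(s) at p < %g)\n",
              x$category, nrow(x$clusters), x$alpha))
  invisible(x)
}

#' Estimate the template-to-stack transform for region labelling
#'
#' Registers the template's baseline pressure image to a stack's reference
#' print so that region masks can be carried into the registered frame.
#'
#' @param template A `region_template` (same side as the stack's foot after
#'   mirroring).
#' @param stack A `registered_stack`.
#' @return `list(theta, dr, dc)` in the [resample_rigid()] convention.
#' @export
align_template_to_stack <- function(template, stack) {
  ref <- stack$prints[[1]]
  fit <- register_one(template$baseline, ref,
                      support_centroid(ref > 0),
                      principal_angle(ref > 0))
  if (is.null(fit)) {
    stop_hoofpspm("template could not be aligned to the stack reference.",
                  "hoofpspm_registration_contract")
  }
  list(theta = fit$par[1], dr = fit$par[2], dc = fit$par[3])
}
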