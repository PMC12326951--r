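#' Build a solar-surface region template for a fore foot
#'
#' Constructs a gridded template of the solar (ground-contact) surface of an
#' equine fore foot at pressure-mat resolution: a rounded hoof outline with a
#' one-sensel hoof-wall rim, a caudal-central V-shaped frog, and a partition
#' of the remaining sole into toe, medial quarter, lateral quarter and heel
#' regions.  The template carries a baseline peak-pressure level (kPa) per
#' region and is the generative substrate for [simulate_strike()].
#'
#' Grid convention: row 1 is the toe (dorsal) edge, the last row the heels;
#' for a left foot column 1 is the lateral side and the last column medial.
#' Right-foot templates are produced by [mirror_template()].
#'
#' @param dims Integer vector `c(rows, cols)` of the sensel grid.
#' @param pitch Sensel pitch in cm (centre-to-centre spacing).
#' @param shape Named list of outline parameters in cm / dimensionless:
#'   `width_cm`, `length_cm` (outline extents), `squareness` (superellipse
#'   exponent), `frog_width_frac` (frog base half-width as a fraction of
#'   outline width), `frog_apex_frac`, `frog_heel_frac` (frog apex / base
#'   positions along the toe-heel axis, as fractions in \[-0.5, 0.5\] of the
#'   outline length, 0 = centre, positive = caudal).
#' @param baselines Named numeric vector of baseline peak pressures (kPa) for
#'   `wall`, `sole` and `frog`.
#' @param side `"left"` or `"right"` (right templates are mirrored left ones).
#'
#' @return An object of class `region_template`: list with `dims`, `pitch`,
#'   `support` (logical matrix), `regions` (named list of disjoint logical
#'   masks `wall`, `frog`, `toe`, `medial_quarter`, `lateral_quarter`,
#'   `heel` whose union is the support), `sole` (union of the four sole
#'   sub-regions), `baseline` (kPa matrix) and `side`.
#' @export
#' @examples
#' tpl <- make_region_template()
#' sum(tpl$support)            # support sensels
#' sapply(tpl$regions, sum)    # region sizes
make_region_template <- function(dims = c(26L, 18L),
                                 pitch = 1.2,
                                 shape = list(),
                                 baselines = c(wall = 400, sole = 250, frog = 160),
                                 side = c("left", "right")) {
  side <- match.arg(side)
  if (length(dims) != 2L || any(!is.finite(dims)) || any(dims < 4)) {
    stop_hoofpspm("`dims` must be two positive grid sizes (>= 4).",
                  "hoofpspm_invalid_config")
  }
  dims <- as.integer(dims)
  check_number(pitch, "pitch", lower = 0, strict_lower = TRUE)
  shp <- utils::modifyList(list(
    width_cm = 13, length_cm = 16, squareness = 2.5,
    frog_width_frac = 0.22, frog_apex_frac = -0.12, frog_heel_frac = 0.42
  ), shape)
  for (nm in c("width_cm", "length_cm"))
    check_number(shp[[nm]], nm, lower = 0, strict_lower = TRUE)
  if (shp$frog_width_frac <= 0 || shp$frog_heel_frac <= shp$frog_apex_frac) {
    stop_hoofpspm("frog shape parameters give a zero-area frog region.",
                  "hoofpspm_invalid_config")
  }
  if (!all(c("wall", "sole", "frog") %in% names(baselines)) ||
      any(baselines[c("wall", "sole", "frog")] <= 0)) {
    stop_hoofpspm("`baselines` must give positive wall, sole and frog levels.",
                  "hoofpspm_invalid_config")
  }

  nr <- dims[1]; nc <- dims[2]
  # sensel-centre coordinates in cm, origin at grid centre;
  # y runs toe (negative) -> heel (positive), x lateral -> medial (left foot)
  y <- (seq_len(nr) - (nr + 1) / 2) * pitch
  x <- (seq_len(nc) - (nc + 1) / 2) * pitch
  Y <- matrix(y, nr, nc)
  X <- matrix(x, nr, nc, byrow = TRUE)

  a <- shp$width_cm / 2; b <- shp$length_cm / 2; p <- shp$squareness
  support <- (abs(X / a)^p + abs(Y / b)^p) <= 1
  if (!any(support)) {
    stop_hoofpspm("outline produced an empty support; enlarge dims or shape.",
                  "hoofpspm_invalid_config")
  }
  if (any(support[1, ]) || any(support[nr, ]) ||
      any(support[, 1]) || any(support[, nc])) {
    stop_hoofpspm(
      "hoof outline touches the grid boundary; enlarge `dims` or shrink the outline.",
      "hoofpspm_invalid_config")
  }

  inner <- erode4(support)         # support minus the one-sensel rim
  wall <- support & !inner
  core <- erode4(inner)            # keeps the frog clear of the wall rim

  y_a <- shp$frog_apex_frac * shp$length_cm
  y_h <- shp$frog_heel_frac * shp$length_cm
  w_base <- shp$frog_width_frac * shp$width_cm
  frac <- pmin(pmax((Y - y_a) / (y_h - y_a), 0), 1)
  halfw <- pmax(w_base * frac, 0.55 * pitch)   # solid spine at the apex
  frog <- core & (Y >= y_a - 0.5 * pitch) & (Y <= y_h) & (abs(X) <= halfw)
  if (!any(frog)) {
    stop_hoofpspm("frog region has zero area at this resolution.",
                  "hoofpspm_invalid_config")
  }
  if (!is_connected4(frog)) {
    stop_hoofpspm("frog region is disconnected at this resolution; adjust shape.",
                  "hoofpspm_invalid_config")
  }

  sole <- inner & !frog
  toe_band <- Y <= -0.18 * shp$length_cm
  heel_band <- Y >= 0.30 * shp$length_cm
  lateral_half <- X < 0            # left foot: lateral = low columns
  regions <- list(
    wall = wall,
    frog = frog,
    toe = sole & toe_band,
    medial_quarter = sole & !toe_band & !heel_band & !lateral_half,
    lateral_quarter = sole & !toe_band & !heel_band & lateral_half,
    heel = sole & heel_band
  )

  baseline <- matrix(0, nr, nc)
  baseline[sole] <- baselines[["sole"]]
  baseline[wall] <- baselines[["wall"]]
  baseline[frog] <- baselines[["frog"]]

  tpl <- structure(
    list(dims = dims, pitch = pitch, shape = shp, support = support,
         regions = regions, sole = sole, baseline = baseline, side = "left"),
    class = "region_template"
  )
  if (side == "right") tpl <- mirror_template(tpl)
  tpl
}

#' Mirror a region template about the medio-lateral axis
#'
#' Produces the contralateral template by flipping columns; medial and
#' lateral quarter labels swap so the anatomy stays truthful.
#'
#' @param template A `region_template`.
#' @return A `region_template` for the opposite side.
#' @export
mirror_template <- function(template) {
  stopifnot(inherits(template, "region_template"))
  flip <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  template$support <- flip(template$support)
  template$sole <- flip(template$sole)
  template$baseline <- flip(template$baseline)
  template$regions <- lapply(template$regions, flip)
  nm <- names(template$regions)
  nm[nm == "medial_quarter"] <- ".tmp"
  nm[nm == "lateral_quarter"] <- "medial_quarter"
  nm[nm == ".tmp"] <- "lateral_quarter"
  names(template$regions) <- nm
  template$regions <- template$regions[c("wall", "frog", "toe",
                                         "medial_quarter", "lateral_quarter",
                                         "heel")]
  template$side <- if (identical(template$side, "left")) "right" else "left"
  template
}

#' @export
print.region_template <- function(x, ...) {
  cat(sprintf(
    "<region_template> %d x %d sensels @ %.2f cm pitch (%s foot)\n",
    x$dims[1], x$dims[2], x$pitch, x$side))
  cat(sprintf("  support: %d sensels (%.1f cm^2); regions: %s\n",
              sum(x$support), sum(x$support) * x$pitch^2,
              paste(sprintf("%s=%d", names(x$regions),
                            vapply(x$regions, sum, 1L)), collapse = " ")))
  invisible(x)
}

#' @rdname tidy_prints
#' @method tidy region_template
#' @export
tidy.region_template <- function(x, ...) {
  idx <- which(x$support, arr.ind = TRUE)
  region <- rep(NA_character_, nrow(idx))
  for (nm in names(x$regions)) {
    hit <- x$regions[[nm]][idx]
    region[hit] <- nm
  }
  tibble(row = as.integer(idx[, 1]), col = as.integer(idx[, 2]),
         region = region, baseline_kpa = x$baseline[idx])
}

# --- small binary-morphology helpers (4-neighbour) -------------------------

erode4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  up <- rbind(mask[-1, , drop = FALSE], FALSE)
  down <- rbind(FALSE, mask[-nr, , drop = FALSE])
  left <- cbind(mask[, -1, drop = FALSE], FALSE)
  right <- cbind(FALSE, mask[, -nc, drop = FALSE])
  mask & up & down & left & right
}

is_connected4 <- function(mask) {
  ids <- which(mask)
  if (length(ids) == 0L) return(FALSE)
  comp <- label_components4(mask)
  max(comp$label) == 1L
}

# label connected components (4-neighbour) of a logical matrix by iterative
# min-label propagation; exact, and fast on the small grids used here
label_components4 <- function(mask) {
  ids <- which(mask)
  k <- length(ids)
  if (k == 0L) return(list(ids = integer(), label = integer(), n = 0L,
                           row = integer(), col = integer()))
  nr <- nrow(mask); nc <- ncol(mask)
  L <- matrix(Inf, nr, nc)
  L[ids] <- seq_len(k)
  repeat {
    up <- rbind(L[-1, , drop = FALSE], Inf)
    down <- rbind(Inf, L[-nr, , drop = FALSE])
    left <- cbind(L[, -1, drop = FALSE], Inf)
    right <- cbind(Inf, L[, -nc, drop = FALSE])
    Lnew <- pmin(L, up, down, left, right)
    Lnew[!mask] <- Inf
    if (identical(Lnew, L)) break
    L <- Lnew
  }
  lab <- match(L[ids], sort(unique(L[ids])))
  list(ids = ids, label = lab, n = max(lab),
       row = (ids - 1L) %% nr + 1L, col = (ids - 1L) %/% nr + 1L)
}
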