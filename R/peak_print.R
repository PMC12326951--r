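#' Construct a peak-pressure print
#'
#' A peak print is one foot-strike's per-sensel maximum pressure image (kPa)
#' together with its strike metadata.  This is the unit of analysis for the
#' topographic comparison of before- and after-trimming conditions.
#'
#' @param pressure Numeric matrix of peak pressures (kPa), all values >= 0.
#' @param pitch Sensel pitch in cm.
#' @param horse_id,foot_id Identifiers.
#' @param side `"left"` or `"right"`.
#' @param condition `"before"` or `"after"` (trimming).
#' @param strike_id Strike index within foot and condition.
#' @param mirrored Has the print been flipped medio-laterally?
#' @param valid Validity flag (see [validate_strike()]); `NA` = not yet checked.
#' @return An object of class `peak_print`.
#' @export
peak_print <- function(pressure, pitch = 1.2, horse_id = NA_character_,
                       foot_id = NA_character_, side = NA_character_,
                       condition = NA_character_, strike_id = NA_integer_,
                       mirrored = FALSE, valid = NA) {
  if (!is.matrix(pressure) || !is.numeric(pressure)) {
    stop_hoofpspm("`pressure` must be a numeric matrix.", "hoofpspm_format")
  }
  if (any(pressure < 0, na.rm = TRUE)) {
    stop_hoofpspm("peak pressures must be non-negative.", "hoofpspm_format")
  }
  structure(
    list(pressure = pressure, pitch = pitch, horse_id = horse_id,
         foot_id = foot_id, side = side, condition = condition,
         strike_id = strike_id, mirrored = mirrored, valid = valid),
    class = "peak_print"
  )
}

#' @export
print.peak_print <- function(x, ...) {
  cat(sprintf(
    "<peak_print> %d x %d sensels, foot %s (%s, %s), strike %s%s\n",
    nrow(x$pressure), ncol(x$pressure),
    x$foot_id %||% NA, x$side, x$condition, x$strike_id,
    if (isTRUE(x$mirrored)) " [mirrored]" else ""))
  cat(sprintf("  support %d sensels, max %.0f kPa, valid = %s\n",
              sum(x$pressure > 0), max(x$pressure), x$valid))
  invisible(x)
}

#' Tidy pressure images into long tibbles
#'
#' `tidy()` methods for the image-shaped objects return one row per sensel
#' so results drop straight into dplyr/ggplot2 workflows.
#'
#' @param x A `region_template`, `peak_print` or `t_field`.
#' @param ... Unused.
#' @return A tibble with `row`, `col` and object-specific value columns.
#' @name tidy_prints
NULL

#' @rdname tidy_prints
#' @method tidy peak_print
#' @export
tidy.peak_print <- function(x, ...) {
  idx <- which(x$pressure >= 0, arr.ind = TRUE)
  tibble(row = as.integer(idx[, 1]), col = as.integer(idx[, 2]),
         pressure_kpa = x$pressure[idx],
         condition = x$condition, strike_id = x$strike_id)
}

#' Collapse a frame sequence to its peak-pressure print
#'
#' Each sensel of the output is the maximum pressure that sensel saw across
#' the stance-phase frame sequence of one strike.
#'
#' @param frames A list of numeric matrices (one per frame, constant dims),
#'   or a 3-d array with frames along the third margin.
#' @param metadata Named list of strike metadata passed through to the print
#'   (`horse_id`, `foot_id`, `side`, `condition`, `strike_id`, `pitch`).
#' @return A `peak_print` (validity unset; see [validate_strike()]).
#' @export
#' @examples
#' f <- list(matrix(0:3, 2), matrix(c(5, 0, 1, 1), 2))
#' extract_peak_print(f)$pressure
extract_peak_print <- function(frames, metadata = list()) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  }
  if (!is.list(frames) || length(frames) == 0L) {
    stop_hoofpspm("`frames` must be a non-empty list of pressure matrices.",
                  "hoofpspm_empty_input")
  }
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), TRUE))) {
    stop_hoofpspm("all frames in a recording must share the same grid dims.",
                  "hoofpspm_format")
  }
  peak <- Reduce(pmax, frames)
  md <- utils::modifyList(
    list(pitch = 1.2, horse_id = NA_character_, foot_id = NA_character_,
         side = NA_character_, condition = NA_character_,
         strike_id = NA_integer_),
    metadata)
  peak_print(peak, pitch = md$pitch, horse_id = md$horse_id,
             foot_id = md$foot_id, side = md$side, condition = md$condition,
             strike_id = md$strike_id)
}

#' Flag incomplete strikes
#'
#' A strike is valid only when the whole foot is on the mat: the print's
#' support must be non-empty and must not touch the outermost row or column
#' of the grid (a support pixel on the boundary means the foot was clipped).
#'
#' @param print A `peak_print`.
#' @return The print with its `valid` flag set.
#' @export
validate_strike <- function(print) {
  stopifnot(inherits(print, "peak_print"))
  m <- print$pressure
  supp <- m > 0
  nr <- nrow(m); nc <- ncol(m)
  clipped <- any(supp[1, ]) || any(supp[nr, ]) ||
    any(supp[, 1]) || any(supp[, nc])
  print$valid <- any(supp) && !clipped
  print
}

#' Mirror a print about the medio-lateral axis
#'
#' Right-fore prints are flipped column-wise so both feet share one
#' anatomical frame (toe-heel axis preserved, medial/lateral swapped); the
#' `mirrored` flag records the flip and mirroring twice restores the
#' original orientation.
#'
#' @param print A `peak_print`.
#' @return The mirrored `peak_print`.
#' @export
mirror_print <- function(print) {
  stopifnot(inherits(print, "peak_print"))
  print$pressure <- print$pressure[, rev(seq_len(ncol(print$pressure))),
                                   drop = FALSE]
  print$mirrored <- !isTRUE(print$mirrored)
  print
}
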