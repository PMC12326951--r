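# Plain-text readers and writers: mat-export frame sequences, peak-print
# grids, strike metadata and pipeline configuration files.

#' Read a delimited ASCII pressure-frame export
#'
#' Parses the mat-export dialect used by walkway pressure systems (and by
#' [write_pressure_frames()]): one block per frame, each introduced by a
#' `Frame <k>` header line, followed by comma-separated rows of pressures in
#' kPa, blocks separated by blank lines.  Lines starting with `#` are
#' treated as file-level comments.
#'
#' @param path File path.
#' @return List of numeric matrices (one per frame).
#' @export
#' @examples
#' f <- system.file("extdata", "sample_strike_frames.txt",
#'                  package = "hoofpspm")
#' frames <- read_pressure_frames(f)
#' peak <- extract_peak_print(frames, list(condition = "before"))
#' peak
read_pressure_frames <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  frames <- list(); rows <- list()
  flush <- function() {
    if (length(rows)) {
      frames[[length(frames) + 1L]] <<- do.call(rbind, rows)
      rows <<- list()
    }
  }
  for (ln in lines) {
    if (grepl("^\\s*$", ln)) { flush(); next }
    if (grepl("^\\s*Frame", ln, ignore.case = TRUE)) { flush(); next }
    rows[[length(rows) + 1L]] <- as.numeric(strsplit(trimws(ln), ",")[[1]])
  }
  flush()
  if (!length(frames)) {
    stop_hoofpspm("no frames found in file.", "hoofpspm_empty_input")
  }
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), TRUE))) {
    stop_hoofpspm("frames in one recording must share grid dims.",
                  "hoofpspm_format")
  }
  frames
}

#' @rdname read_pressure_frames
#' @param frames List of numeric matrices.
#' @param path Output file path.
#' @export
write_pressure_frames <- function(frames, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(frames)) {
    writeLines(sprintf("Frame %d", i), con)
    utils::write.table(frames[[i]], con, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    writeLines("", con)
  }
  invisible(path)
}

#' Write / read a peak print as a delimited grid
#'
#' The grid is comma-separated; strike metadata travel in `# key: value`
#' header lines so a print round-trips losslessly through plain text.
#'
#' @param print A `peak_print`.
#' @param path File path.
#' @return `write_peak_print()` the path, invisibly; `read_peak_print()` a
#'   `peak_print`.
#' @export
write_peak_print <- function(print, path) {
  stopifnot(inherits(print, "peak_print"))
  hdr <- sprintf("# %s: %s",
                 c("pitch", "horse_id", "foot_id", "side", "condition",
                   "strike_id", "mirrored", "valid"),
                 c(print$pitch, print$horse_id, print$foot_id, print$side,
                   print$condition, print$strike_id, print$mirrored,
                   print$valid))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(print$pressure, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_print
#' @export
read_peak_print <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#\\s*", "", hdr), ":\\s*")
  meta <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  mat <- do.call(rbind, lapply(body, function(ln) {
    as.numeric(strsplit(trimws(ln), ",")[[1]])
  }))
  as_lgl <- function(x) if (is.na(x) || x == "NA") NA else as.logical(x)
  peak_print(mat,
             pitch = as.numeric(meta[["pitch"]]),
             horse_id = meta[["horse_id"]], foot_id = meta[["foot_id"]],
             side = meta[["side"]], condition = meta[["condition"]],
             strike_id = as.integer(meta[["strike_id"]]),
             mirrored = isTRUE(as_lgl(meta[["mirrored"]])),
             valid = as_lgl(meta[["valid"]]))
}

#' Strike metadata as CSV
#'
#' @param prints List of `peak_print`s.
#' @param path Output path.
#' @return The metadata tibble (columns `horse_id`, `foot_id`, `side`,
#'   `condition`, `strike_id`, `valid`), written to `path` when given.
#' @export
strike_metadata <- function(prints, path = NULL) {
  md <- bind_rows(lapply(prints, function(p) {
    tibble(horse_id = p$horse_id, foot_id = p$foot_id, side = p$side,
           condition = p$condition, strike_id = p$strike_id,
           valid = p$valid)
  }))
  if (!is.null(path)) readr::write_csv(md, path)
  md
}
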