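# Tab-separated trajectory dialect, modelled on common motion-capture
# exports: metadata header lines (KEY<TAB>value), then one header row with
# X/Y/Z triplet columns per marker, then one row per frame.
#
#   FREQUENCY   120
#   UNITS       m
#   toe_L_X  toe_L_Y  toe_L_Z  toe_R_X ...
#   0.012    -0.5     0.031    ...

#' Write a recording to the tabular trajectory format
#'
#' @param rec a [trial_recording()].
#' @param path output file path.
#' @param units `"m"` or `"mm"`; coordinates are converted on write.
#' @param digits significant digits written (default 7).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, units = c("m", "mm"), digits = 7) {
  units <- match.arg(units)
  pos <- rec$positions
  if (units == "mm") pos <- pos * 1000
  nm <- dimnames(pos)[[2]]
  wide <- matrix(aperm(pos, c(1, 3, 2)), nrow = dim(pos)[1])
  colnames(wide) <- as.vector(t(outer(nm, c("_X", "_Y", "_Z"), paste0)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("FREQUENCY\t%s", format(rec$rate, digits = 12)),
               sprintf("UNITS\t%s", units)), con)
  writeLines(paste(colnames(wide), collapse = "\t"), con)
  body <- apply(wide, 1, function(r) {
    paste(ifelse(is.na(r), "NA", formatC(r, digits = digits, format = "g")),
          collapse = "\t")
  })
  writeLines(body, con)
  invisible(path)
}

read_trajectory_tsv <- function(path, units = NULL, aliases = default_marker_aliases()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_exerstep("EmptyRecording", sprintf("empty file: %s", path))

  rate <- NA_real_
  i <- 1L
  while (i <= length(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    key <- toupper(trimws(f[1]))
    if (key %in% c("FREQUENCY", "RATE", "SAMPLE_RATE")) {
      rate <- suppressWarnings(as.numeric(f[2]))
      if (!is_scalar_number(rate) || rate <= 0) {
        stop_exerstep("FormatError", sprintf("unparseable sampling rate: '%s'", f[2]))
      }
    } else if (key == "UNITS" && is.null(units)) {
      units <- tolower(trimws(f[2]))
    } else if (!key %in% c("UNITS")) {
      break  # first non-metadata line is the column header
    }
    i <- i + 1L
  }
  if (is.na(rate)) stop_exerstep("FormatError", "no FREQUENCY metadata line found")
  if (is.null(units)) units <- "m"
  if (!units %in% c("m", "mm")) {
    stop_exerstep("FormatError", sprintf("unsupported units '%s'", units))
  }
  if (i > length(lines)) stop_exerstep("EmptyRecording", "no data header found")

  header <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
  if (length(header) %% 3 != 0 || !length(header)) {
    stop_exerstep("FormatError", "column header is not X/Y/Z triplets")
  }
  base <- sub("_[XYZxyz]$", "", header)
  markers <- base[seq(1, length(base), by = 3)]
  if (!all(base == rep(markers, each = 3))) {
    stop_exerstep("FormatError", "columns are not grouped as per-marker X/Y/Z triplets")
  }
  markers <- canonicalize_labels(markers, aliases)

  data_lines <- lines[-seq_len(i)]
  if (!length(data_lines)) stop_exerstep("EmptyRecording", "file has 0 frames")
  vals <- strsplit(data_lines, "\t", fixed = TRUE)
  ncol <- length(header)
  bad <- which(lengths(vals) != ncol)
  if (length(bad)) {
    stop_exerstep("FormatError",
                  sprintf("frame row %d has %d fields, expected %d",
                          bad[1], lengths(vals)[bad[1]], ncol))
  }
  wide <- matrix(suppressWarnings(as.numeric(unlist(vals))),
                 nrow = length(vals), ncol = ncol, byrow = TRUE)
  if (units == "mm") wide <- wide / 1000
  pos <- array(wide, dim = c(nrow(wide), 3, length(markers)))
  pos <- aperm(pos, c(1, 3, 2))
  dimnames(pos) <- list(NULL, markers, c("x", "y", "z"))
  trial_recording(pos, rate = rate)
}

#' Load a marker trajectory recording
#'
#' Reads a trajectory file into a [trial_recording()] in lab-frame metres.
#' Millimetre coordinates are converted to metres; marker labels are mapped
#' onto the canonical 22-marker set through an alias table.
#'
#' @param path file path.
#' @param format `"tsv"`, `"c3d"` or `"auto"` (by file extension).
#' @param units coordinate units, `"m"` or `"mm"`; `NULL` (default) trusts
#'   the file's own metadata and falls back to metres.
#' @param aliases marker alias table, see [default_marker_aliases()].
#' @param require_full if `TRUE`, fail with a `MarkerSetMismatch` error
#'   unless all 22 canonical markers are present after aliasing.
#' @return A [trial_recording()].
#' @export
#' @examples
#' rec <- synthesize_markers(empty_movement_plan(1), noise_sd = 0)
#' f <- tempfile(fileext = ".tsv")
#' write_recording(rec, f)
#' rec2 <- load_recording(f)
#' all.equal(rec$positions, rec2$positions, tolerance = 1e-6)
load_recording <- function(path, format = c("auto", "tsv", "c3d"),
                           units = NULL, aliases = default_marker_aliases(),
                           require_full = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_exerstep("FormatError", sprintf("file not found: %s", path))
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "c3d") "c3d" else "tsv"
  }
  rec <- switch(format,
    tsv = read_trajectory_tsv(path, units = units, aliases = aliases),
    c3d = read_c3d(path, units = units, aliases = aliases)
  )
  if (require_full) {
    miss <- setdiff(exerstep_markers(), rec$markers)
    if (length(miss)) {
      stop_exerstep("MarkerSetMismatch",
                    sprintf("missing required marker(s) after aliasing: %s",
                            paste(miss, collapse = ", ")))
    }
  }
  rec
}
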