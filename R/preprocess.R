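#' Interpolate short occlusion gaps
#'
#' Linearly interpolates missing spans no longer than `max_gap` per marker
#' and coordinate; longer spans (and spans touching the recording ends,
#' which cannot be interpolated) are left missing and listed in the gap
#' report. Observed samples are never altered, so the operation is
#' idempotent. The default `max_gap` of 0.1 s is deliberately shorter than
#' the minimum step duration relevant to detection, so interpolation cannot
#' fabricate an event.
#'
#' @param rec a [trial_recording()].
#' @param max_gap longest gap to fill, s.
#' @return The recording with gaps filled; the gap report (a `data.frame`
#'   with `marker`, `coord`, `start_frame`, `n_frames`, `filled`) is
#'   attached as attribute `"gap_report"`.
#' @export
fill_gaps <- function(rec, max_gap = 0.1) {
  check_scalar_number(max_gap, "max_gap", 0)
  max_frames <- floor(max_gap * rec$rate)
  report <- list()
  pos <- rec$positions
  for (m in seq_along(rec$markers)) {
    for (k in 1:3) {
      v <- pos[, m, k]
      if (!anyNA(v)) next
      runs <- logical_runs(is.na(v))
      for (r in seq_len(nrow(runs))) {
        i0 <- runs[r, 1]; i1 <- runs[r, 2]
        n <- i1 - i0 + 1L
        interior <- i0 > 1L && i1 < length(v)
        fill <- interior && n <= max_frames
        if (fill) {
          v[i0:i1] <- approx(x = c(i0 - 1L, i1 + 1L), y = v[c(i0 - 1L, i1 + 1L)],
                             xout = i0:i1)$y
        }
        report[[length(report) + 1L]] <- data.frame(
          marker = rec$markers[m], coord = c("x", "y", "z")[k],
          start_frame = i0, n_frames = n, filled = fill
        )
      }
      pos[, m, k] <- v
    }
  }
  out <- trial_recording(pos, rec$rate, rec$meta)
  attr(out, "gap_report") <- if (length(report)) do.call(rbind, report) else
    data.frame(marker = character(), coord = character(),
               start_frame = integer(), n_frames = integer(), filled = logical())
  out
}

#' Validate a recording
#'
#' Report-only checks: marker-set completeness against the canonical 22
#' markers, per-marker missing-data fraction, rate plausibility, and whether
#' the sternum stays within a +/- 5 m sanity bound horizontally.
#'
#' @param rec a [trial_recording()].
#' @return List of class `recording_validation`: `complete`,
#'   `missing_markers`, `missing_fraction` (named per marker),
#'   `rate_ok`, `sternum_in_bounds`, `ok` (all checks pass).
#' @export
validate_recording <- function(rec) {
  canon <- exerstep_markers()
  missing_markers <- setdiff(canon, rec$markers)
  frac <- vapply(rec$markers, function(m) {
    mean(is.na(rec$positions[, m, ]))
  }, 0)
  rate_ok <- is_scalar_number(rec$rate) && rec$rate > 0 && rec$rate <= 2000
  sternum_ok <- if ("sternum" %in% rec$markers) {
    xy <- marker_xyz(rec, "sternum")[, 1:2]
    all(abs(xy) < 5, na.rm = TRUE)
  } else NA
  structure(list(
    complete = length(missing_markers) == 0L,
    missing_markers = missing_markers,
    missing_fraction = frac,
    rate_ok = rate_ok,
    sternum_in_bounds = sternum_ok,
    ok = length(missing_markers) == 0L && rate_ok && isTRUE(sternum_ok)
  ), class = "recording_validation")
}

#' @export
print.recording_validation <- function(x, ...) {
  cat(sprintf("<recording_validation> %s\n", if (x$ok) "all checks pass" else "issues found"))
  if (!x$complete) {
    cat("  missing markers:", paste(x$missing_markers, collapse = ", "), "\n")
  }
  worst <- sort(x$missing_fraction, decreasing = TRUE)
  worst <- worst[worst > 0]
  if (length(worst)) {
    cat(sprintf("  markers with missing data: %s\n",
                paste(sprintf("%s %.1f%%", names(head(worst, 5)), 100 * head(worst, 5)),
                      collapse = ", ")))
  }
  if (!isTRUE(x$sternum_in_bounds)) cat("  sternum out of sanity bounds\n")
  invisible(x)
}
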