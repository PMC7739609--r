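#' Construct a trial recording
#'
#' A `trial_recording` holds time-synchronous 3D positions (metres, lab
#' frame) for a set of named markers sampled at a fixed rate, plus trial
#' metadata. The lab frame is right-handed with X medial-lateral (positive to
#' the player's right when facing the screen), Y anterior-posterior (positive
#' toward the screen) and Z vertical; the origin sits at the centre of the
#' active play area on the floor, so the 2 x 2 m area is
#' X, Y in \[-1, 1\]. Missing samples are `NA` (never zero: zero is a valid
#' coordinate).
#'
#' @param positions numeric array `frames x markers x 3`, metres, with marker
#'   labels as second dimnames and `c("x","y","z")` third.
#' @param rate sampling frequency in Hz (> 0).
#' @param meta named list of trial metadata (participant, gender, speed,
#'   obstacles, repetition, ...); free-form.
#' @return Object of class `trial_recording` with fields `positions`,
#'   `markers`, `rate`, `duration` (= frames / rate, seconds) and `meta`.
#' @export
trial_recording <- function(positions, rate, meta = list()) {
  check_scalar_number(rate, "rate", min = 0, strict = TRUE)
  if (length(dim(positions)) != 3L || dim(positions)[3] != 3L) {
    stop_exerstep("FormatError", "`positions` must be a frames x markers x 3 array")
  }
  if (is.null(dimnames(positions)[[2]])) {
    stop_exerstep("FormatError", "`positions` must carry marker labels as dimnames")
  }
  dimnames(positions)[[3]] <- c("x", "y", "z")
  n <- dim(positions)[1]
  if (n == 0L) stop_exerstep("EmptyRecording", "recording has zero frames")
  structure(
    list(
      positions = positions,
      markers = dimnames(positions)[[2]],
      rate = as.numeric(rate),
      duration = n / as.numeric(rate),
      meta = meta
    ),
    class = "trial_recording"
  )
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording> %d markers, %d frames @ %g Hz (%.2f s)\n",
    length(x$markers), n_frames(x), x$rate, x$duration
  ))
  if (length(x$meta)) {
    keep <- intersect(c("participant", "gender", "speed", "obstacles", "repetition"),
                      names(x$meta))
    if (length(keep)) {
      cat("  meta:", paste(sprintf("%s=%s", keep, unlist(x$meta[keep])),
                           collapse = ", "), "\n")
    }
  }
  miss <- mean(is.na(x$positions))
  if (miss > 0) cat(sprintf("  missing: %.1f%% of samples\n", 100 * miss))
  invisible(x)
}

n_frames <- function(rec) dim(rec$positions)[1]

rec_times <- function(rec) (seq_len(n_frames(rec)) - 1L) / rec$rate

#' Extract one marker's trajectory
#'
#' @param rec a [trial_recording()].
#' @param marker canonical marker label.
#' @return `frames x 3` numeric matrix (columns x, y, z, metres).
#' @export
marker_xyz <- function(rec, marker) {
  if (!marker %in% rec$markers) {
    stop_exerstep("MarkerSetMismatch",
                  sprintf("marker '%s' not present in recording", marker))
  }
  m <- rec$positions[, marker, , drop = FALSE]
  dim(m) <- c(dim(m)[1], 3L)
  colnames(m) <- c("x", "y", "z")
  m
}

has_markers <- function(rec, markers) all(markers %in% rec$markers)

require_markers <- function(rec, markers) {
  miss <- setdiff(markers, rec$markers)
  if (length(miss)) {
    stop_exerstep("MarkerSetMismatch",
                  sprintf("recording lacks required marker(s): %s",
                          paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}
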