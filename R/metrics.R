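#' Per-foot step metrics
#'
#' @param steps per-foot step tables, as from [detect_steps()].
#' @param trial_time trial duration in seconds -- by convention the full
#'   motion-capture duration, which keeps running through game pauses.
#' @return `data.frame` with one row per foot: `foot`, `n_steps`,
#'   `mean_step_size` (m; `NA` when there are no steps) and `cadence`
#'   (steps per minute).
#' @export
#' @examples
#' steps <- list(left = data.frame(start = 1:30, end = 1:30 + 0.3,
#'                                 size = rep(0.2, 30)),
#'               right = data.frame(start = numeric(), end = numeric(),
#'                                  size = numeric()))
#' step_metrics(steps, trial_time = 120)   # cadence 15 and 0
step_metrics <- function(steps, trial_time) {
  check_scalar_number(trial_time, "trial_time", 0, strict = TRUE)
  rows <- lapply(c("left", "right"), function(f) {
    s <- steps[[f]]
    n <- if (is.null(s)) 0L else nrow(s)
    data.frame(
      foot = f, n_steps = n,
      mean_step_size = if (n) mean(s$size) else NA_real_,
      cadence = 60 * n / trial_time
    )
  })
  do.call(rbind, rows)
}

#' Per-foot single-leg support metrics
#'
#' @param support per-foot support interval matrices, as from
#'   [derive_single_support()].
#' @inheritParams step_metrics
#' @return `data.frame` per foot with `n_intervals`, `mean_duration` (s; `NA`
#'   when empty), `total` (s) and `ratio` (accumulated single-support time
#'   over trial time).
#' @export
support_metrics <- function(support, trial_time) {
  check_scalar_number(trial_time, "trial_time", 0, strict = TRUE)
  rows <- lapply(c("left", "right"), function(f) {
    m <- support[[f]]
    n <- if (is.null(m)) 0L else nrow(m)
    lens <- if (n) m[, 2] - m[, 1] else numeric()
    data.frame(
      foot = f, n_intervals = n,
      mean_duration = if (n) mean(lens) else NA_real_,
      total = sum(lens),
      ratio = sum(lens) / trial_time
    )
  })
  do.call(rbind, rows)
}

#' Arm-lift frequency
#'
#' Lifts per minute, per side and combined. The trial time is the full
#' recording duration, so frequencies stay comparable across trials whose
#' game clock paused on error messages. Events with `side = "both"` count
#' toward both sides but once toward the combined rate.
#'
#' @param lifts arm-lift table, as from [detect_arm_lifts()].
#' @inheritParams step_metrics
#' @return Named numeric vector: `left`, `right`, `combined` (min^-1).
#' @export
arm_lift_frequency <- function(lifts, trial_time) {
  check_scalar_number(trial_time, "trial_time", 0, strict = TRUE)
  n_side <- function(s) sum(lifts$side %in% c(s, "both"))
  c(left = 60 * n_side("left") / trial_time,
    right = 60 * n_side("right") / trial_time,
    combined = 60 * nrow(lifts) / trial_time)
}

#' Sternum occupancy heatmap
#'
#' 2D histogram of the sternum marker's horizontal position: the standard
#' summary of where a player stood during a trial. Cells are half-open
#' `[lo, hi)` except the last along each axis, which is closed, so points on
#' the upper extent edge are counted.
#'
#' @param rec a [trial_recording()] containing a `sternum` marker.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in metres. The default
#'   3 x 3 m window centred on the play area leaves room to observe
#'   excursions beyond the 2 x 2 m active square.
#' @param bins number of cells per axis (default 30).
#' @return List of class `exerstep_heatmap`: `counts` (`bins x bins` matrix,
#'   X along rows), `extent`, `total` (valid sternum frames) and
#'   `out_of_extent`.
#' @export
position_heatmap <- function(rec, extent = c(-1.5, 1.5, -1.5, 1.5), bins = 30) {
  require_markers(rec, "sternum")
  if (length(extent) != 4L || extent[1] >= extent[2] || extent[3] >= extent[4]) {
    stop_exerstep("ConfigError", "`extent` must be c(xmin, xmax, ymin, ymax)")
  }
  xy <- marker_xyz(rec, "sternum")[, 1:2, drop = FALSE]
  ok <- stats::complete.cases(xy)
  xy <- xy[ok, , drop = FALSE]
  bin_of <- function(v, lo, hi) {
    b <- floor((v - lo) / (hi - lo) * bins) + 1L
    b[v == hi] <- bins  # closed upper edge
    b[v < lo | v > hi] <- NA_integer_
    b
  }
  bx <- bin_of(xy[, 1], extent[1], extent[2])
  by <- bin_of(xy[, 2], extent[3], extent[4])
  inside <- !is.na(bx) & !is.na(by)
  counts <- matrix(0L, bins, bins)
  if (any(inside)) {
    tab <- table(factor(bx[inside], levels = seq_len(bins)),
                 factor(by[inside], levels = seq_len(bins)))
    counts <- matrix(as.integer(tab), bins, bins)
  }
  structure(
    list(counts = counts, extent = extent, bins = bins,
         total = nrow(xy), out_of_extent = sum(!inside)),
    class = "exerstep_heatmap"
  )
}

#' @export
print.exerstep_heatmap <- function(x, ...) {
  cat(sprintf("<exerstep_heatmap> %d x %d grid over [%g, %g] x [%g, %g] m; %d frames (%d outside)\n",
              x$bins, x$bins, x$extent[1], x$extent[2], x$extent[3], x$extent[4],
              x$total, x$out_of_extent))
  invisible(x)
}

#' Anterior drift of the trunk
#'
#' Players tend to creep toward the screen over a trial even though the game
#' never asks for it. The statistic is the mean sternum Y over the final
#' `window` seconds minus the mean over the first `window` seconds; positive
#' values mean drift toward the screen.
#'
#' @inheritParams position_heatmap
#' @param window averaging window at each end of the trial, s (default 10).
#' @return Drift in metres.
#' @export
#' @examples
#' # a linear 0 -> 0.5 m ramp over 120 s gives 0.5 * (110/120) = 0.458 m
anterior_drift <- function(rec, window = 10) {
  require_markers(rec, "sternum")
  check_scalar_number(window, "window", 0, strict = TRUE)
  if (rec$duration <= 2 * window) {
    stop_exerstep("InsufficientData",
                  sprintf("trial (%.2f s) shorter than two %g s windows",
                          rec$duration, window))
  }
  y <- marker_xyz(rec, "sternum")[, 2]
  t <- rec_times(rec)
  mean(y[t >= rec$duration - window], na.rm = TRUE) -
    mean(y[t <= window], na.rm = TRUE)
}

#' Compute all per-trial movement characteristics
#'
#' Runs detection and every metric for one recording, yielding the
#' study-style trial summary.
#'
#' @param rec a [trial_recording()] with the full marker set.
#' @param cfg a [detection_config()].
#' @param heatmap_extent passed to [position_heatmap()].
#' @return List of class `trial_metrics` with elements `steps`, `lifts`,
#'   `support`, `per_foot` (merged step and support metrics), `arm_lifts`
#'   (per-side frequencies), `anterior_drift`, `heatmap`, `trial_time`, and
#'   the recording's `meta`.
#' @export
compute_trial_metrics <- function(rec, cfg = detection_config(),
                                  heatmap_extent = c(-1.5, 1.5, -1.5, 1.5)) {
  steps <- detect_steps(rec, cfg)
  lifts <- detect_arm_lifts(rec, cfg)
  support <- derive_single_support(steps, rec$duration)
  per_foot <- merge(step_metrics(steps, rec$duration),
                    support_metrics(support, rec$duration), by = "foot")
  drift <- if (rec$duration > 20) anterior_drift(rec) else NA_real_
  structure(
    list(steps = steps, lifts = lifts, support = support,
         per_foot = per_foot,
         arm_lifts = arm_lift_frequency(lifts, rec$duration),
         anterior_drift = drift,
         heatmap = position_heatmap(rec, heatmap_extent),
         trial_time = rec$duration, meta = rec$meta),
    class = "trial_metrics"
  )
}

#' @export
print.trial_metrics <- function(x, ...) {
  cat(sprintf("<trial_metrics> %.1f s trial\n", x$trial_time))
  print(x$per_foot, row.names = FALSE)
  cat(sprintf("arm lifts/min: L %.2f R %.2f combined %.2f; drift %.3f m\n",
              x$arm_lifts["left"], x$arm_lifts["right"], x$arm_lifts["combined"],
              x$anterior_drift))
  invisible(x)
}
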