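#' Detection configuration
#'
#' Thresholds and numerical choices for step and arm-lift detection. The step
#' criterion follows the study protocol: a step is a displacement of at least
#' `min_displacement` (default 0.03 m) of the foot marker lasting at least
#' `min_duration` (default 0.05 s), with initiation and termination located
#' where the marker's horizontal speed crosses the stationary band
#' 0 +/- `stationary_speed` (default 0.1 m/s). The arm-lift criterion compares
#' wrist height against the mean height of the four head markers.
#'
#' @param min_displacement minimum net horizontal step displacement, m.
#' @param min_duration minimum step duration, s.
#' @param stationary_speed half-width of the stationary velocity band, m/s;
#'   a marker is stationary iff its horizontal speed is below this value.
#' @param foot_marker `"toe"` (default; the operational step definition names
#'   the toe marker) or `"ankle"` (lateral malleolus, as in earlier work).
#' @param filter_cutoff zero-lag low-pass cutoff in Hz applied before
#'   differentiation; `NA` disables filtering.
#' @param min_lift_duration arm lifts shorter than this are discarded, s.
#' @param lift_hysteresis a lift ends only once the wrist has dropped this far
#'   below mean head height, m; suppresses chatter at the boundary.
#' @param merge_bilateral merge overlapping left/right lifts to `side="both"`.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(min_displacement = 0.03,
                             min_duration = 0.05,
                             stationary_speed = 0.1,
                             foot_marker = c("toe", "ankle"),
                             filter_cutoff = 6,
                             min_lift_duration = 0.1,
                             lift_hysteresis = 0.02,
                             merge_bilateral = TRUE) {
  foot_marker <- match.arg(foot_marker)
  check_scalar_number(min_displacement, "min_displacement", 0, strict = TRUE)
  check_scalar_number(min_duration, "min_duration", 0, strict = TRUE)
  check_scalar_number(stationary_speed, "stationary_speed", 0, strict = TRUE)
  check_scalar_number(min_lift_duration, "min_lift_duration", 0)
  check_scalar_number(lift_hysteresis, "lift_hysteresis", 0)
  structure(
    list(min_displacement = min_displacement, min_duration = min_duration,
         stationary_speed = stationary_speed, foot_marker = foot_marker,
         filter_cutoff = filter_cutoff, min_lift_duration = min_lift_duration,
         lift_hysteresis = lift_hysteresis, merge_bilateral = merge_bilateral),
    class = "detection_config"
  )
}

empty_steps <- function() {
  data.frame(foot = character(), start = numeric(), end = numeric(),
             size = numeric())
}

# Maximal runs of TRUE in a logical vector -> matrix [start_idx, end_idx]
logical_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

detect_steps_one <- function(xyz, rate, cfg) {
  kin <- horiz_kinematics(xyz, rate, cfg$filter_cutoff)
  moving <- kin$speed >= cfg$stationary_speed
  runs <- logical_runs(moving)
  if (!nrow(runs)) return(empty_steps()[, -1])
  t0 <- (runs[, 1] - 1L) / rate
  t1 <- (runs[, 2] - 1L) / rate
  size <- sqrt((kin$x[runs[, 2]] - kin$x[runs[, 1]])^2 +
               (kin$y[runs[, 2]] - kin$y[runs[, 1]])^2)
  dur <- (runs[, 2] - runs[, 1]) / rate
  keep <- dur >= cfg$min_duration & size >= cfg$min_displacement & !is.na(size)
  data.frame(start = t0[keep], end = t1[keep], size = size[keep])
}

#' Detect steps from foot-marker trajectories
#'
#' Segments each foot's trajectory into candidate movement bursts -- maximal
#' runs of frames where the horizontal foot-marker speed is at or above the
#' stationary band -- and keeps a burst as a step iff its net horizontal
#' displacement is at least `min_displacement` and its duration at least
#' `min_duration`. Step size is the horizontal Euclidean distance between the
#' positions at burst start and end, capturing sideways and forward
#' components alike.
#'
#' @param rec a [trial_recording()] containing the configured foot markers.
#' @param cfg a [detection_config()].
#' @return A list with elements `left` and `right`, each a `data.frame` with
#'   columns `start`, `end` (s) and `size` (m), ordered by start time.
#' @export
#' @examples
#' gt <- single_step_plan(foot = "right", size = 0.25)
#' rec <- synthesize_markers(gt, noise_sd = 0)
#' detect_steps(rec, detection_config())
detect_steps <- function(rec, cfg = detection_config()) {
  out <- list()
  for (side in c("left", "right")) {
    mk <- paste0(cfg$foot_marker, "_", if (side == "left") "L" else "R")
    require_markers(rec, mk)
    out[[side]] <- detect_steps_one(marker_xyz(rec, mk), rec$rate, cfg)
  }
  out
}

# last-observation-carried-forward over a sparse state vector (NA = keep)
locf <- function(x, init = 0) {
  idx <- cumsum(!is.na(x))
  vals <- c(init, x[!is.na(x)])
  vals[idx + 1L]
}

detect_lifts_one <- function(wrist_z, head_z, times, cfg) {
  up <- wrist_z > head_z
  down <- wrist_z < head_z - cfg$lift_hysteresis
  s <- rep(NA_real_, length(up))
  s[which(down)] <- 0
  s[which(up)] <- 1          # up wins if both (cannot happen for hyst >= 0)
  state <- locf(s, init = 0)
  state[is.na(up)] <- 0
  runs <- logical_runs(state == 1)
  if (!nrow(runs)) return(data.frame(start = numeric(), end = numeric()))
  n <- length(times)
  start <- times[runs[, 1]]
  end <- times[pmin(runs[, 2] + 1L, n)]  # first frame back in the off state
  keep <- (end - start) >= cfg$min_lift_duration
  data.frame(start = start[keep], end = end[keep])
}

#' Detect arm lifts
#'
#' An arm lift is the interval during which a wrist marker (ulna styloid) is
#' higher than the mean height of the four head markers -- the same rule the
#' exergame uses to accept a catch. The lift starts when the wrist rises
#' above mean head height and ends when it falls below mean head height minus
#' `lift_hysteresis`; events shorter than `min_lift_duration` are discarded,
#' and overlapping left/right events are merged to `side = "both"` when
#' `cfg$merge_bilateral` is set.
#'
#' @inheritParams detect_steps
#' @return `data.frame` with columns `side` (`"left"`, `"right"`, `"both"`),
#'   `start`, `end` (s), ordered by start time.
#' @export
detect_arm_lifts <- function(rec, cfg = detection_config()) {
  heads <- paste0(rep(c("head_front", "head_back"), each = 2), c("_L", "_R"))
  require_markers(rec, c(heads, "wrist_L", "wrist_R"))
  hz <- rowMeans(sapply(heads, function(m) marker_xyz(rec, m)[, 3]), na.rm = TRUE)
  times <- rec_times(rec)
  ev <- list()
  for (side in c("left", "right")) {
    wz <- marker_xyz(rec, paste0("wrist_", if (side == "left") "L" else "R"))[, 3]
    d <- detect_lifts_one(wz, hz, times, cfg)
    if (nrow(d)) d$side <- side
    ev[[side]] <- d
  }
  out <- rbind(ev$left, ev$right)
  if (is.null(out) || !nrow(out)) {
    return(data.frame(side = character(), start = numeric(), end = numeric()))
  }
  out <- out[order(out$start), c("side", "start", "end")]
  rownames(out) <- NULL
  if (isTRUE(cfg$merge_bilateral) && nrow(out) > 1L) {
    merged <- out[1, ]
    for (i in 2:nrow(out)) {
      last <- nrow(merged)
      if (out$start[i] < merged$end[last] && out$side[i] != merged$side[last]) {
        merged$end[last] <- max(merged$end[last], out$end[i])
        merged$side[last] <- "both"
      } else {
        merged <- rbind(merged, out[i, ])
      }
    }
    out <- merged
    rownames(out) <- NULL
  }
  out
}

# --- interval arithmetic ----------------------------------------------------

# union of possibly-overlapping [start, end] rows -> disjoint, sorted
interval_union <- function(m) {
  if (is.null(m) || !nrow(m)) return(cbind(start = numeric(), end = numeric()))
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  if (nrow(m) > 1) for (i in 2:nrow(m)) {
    k <- nrow(out)
    if (m[i, 1] <= out[k, 2]) {
      out[k, 2] <- max(out[k, 2], m[i, 2])
    } else {
      out <- rbind(out, m[i, , drop = FALSE])
    }
  }
  colnames(out) <- c("start", "end")
  out
}

# set difference a \ b on disjoint sorted interval matrices
interval_diff <- function(a, b) {
  a <- interval_union(a); b <- interval_union(b)
  if (!nrow(a) || !nrow(b)) return(a)
  res <- list()
  for (i in seq_len(nrow(a))) {
    lo <- a[i, 1]; hi <- a[i, 2]
    for (j in seq_len(nrow(b))) {
      blo <- b[j, 1]; bhi <- b[j, 2]
      if (bhi <= lo || blo >= hi) next
      if (blo > lo) res[[length(res) + 1L]] <- c(lo, blo)
      lo <- max(lo, bhi)
      if (lo >= hi) break
    }
    if (lo < hi) res[[length(res) + 1L]] <- c(lo, hi)
  }
  if (!length(res)) return(cbind(start = numeric(), end = numeric()))
  out <- do.call(rbind, res)
  colnames(out) <- c("start", "end")
  out
}

#' Derive single-leg support intervals from detected steps
#'
#' While one foot is in swing (a detected step) and the other is stationary,
#' the stationary foot is in single-leg support. For stance foot F the
#' support set is the union of the contralateral foot's step intervals minus
#' any overlap with F's own steps (double-swing time is excluded), clipped to
#' the recording.
#'
#' @param steps list with per-foot step tables as returned by
#'   [detect_steps()].
#' @param duration recording duration in seconds.
#' @param exclude_double_swing drop intervals where both feet move at once
#'   (default `TRUE`; the exclusion rule is declared, not inherited).
#' @return List with `left` and `right` matrices of disjoint
#'   `start`/`end` intervals (the stance foot names the element).
#' @export
#' @examples
#' steps <- list(left = data.frame(start = 2.4, end = 2.9, size = 0.2),
#'               right = data.frame(start = 2.0, end = 2.5, size = 0.2))
#' derive_single_support(steps, duration = 120)
derive_single_support <- function(steps, duration, exclude_double_swing = TRUE) {
  check_scalar_number(duration, "duration", 0, strict = TRUE)
  as_mat <- function(d) {
    if (is.null(d) || !nrow(d)) return(cbind(start = numeric(), end = numeric()))
    cbind(start = pmax(0, d$start), end = pmin(duration, d$end))
  }
  L <- as_mat(steps$left); R <- as_mat(steps$right)
  out <- list(
    left = if (exclude_double_swing) interval_diff(R, L) else interval_union(R),
    right = if (exclude_double_swing) interval_diff(L, R) else interval_union(L)
  )
  lapply(out, function(m) m[m[, 2] > m[, 1], , drop = FALSE])
}
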