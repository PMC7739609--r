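#' Default segment geometry for marker synthesis
#'
#' Fixed-offset body model used to render the 22-marker set from a movement
#' plan: marker heights are standard fractions of body height, lateral
#' offsets approximate shoulder/pelvis widths. Deliberately simple -- the
#' detectors only rely on foot-marker kinematics, wrist-vs-head height and
#' the sternum position.
#'
#' @param height body height, m.
#' @return Named list of marker offsets (m) of class `anthropometry`.
#' @export
default_anthropometry <- function(height = 1.71) {
  check_scalar_number(height, "height", 0, strict = TRUE)
  structure(list(
    height = height,
    head_z = 0.94 * height,
    head_dx = 0.08, head_dy = 0.09,
    sternum_z = 0.80 * height, sternum_dy = 0.05,
    shoulder_z = 0.82 * height, shoulder_dx = 0.20,
    elbow_z = 0.63 * height, elbow_dx = 0.26,
    wrist_z = 0.52 * height, wrist_dx = 0.28,
    ilium_z = 0.58 * height, ilium_dx = 0.13, ilium_dy = 0.09,
    thigh_z = 0.45 * height, thigh_dx = 0.12,
    knee_z = 0.28 * height, knee_dx = 0.06,
    ankle_z = 0.05, toe_z = 0.02, toe_dy = 0.15,
    lift_amplitude = 0.15, lift_ramp = 0.3
  ), class = "anthropometry")
}

# per-foot x/y paths from the plan's steps (piecewise minimum-jerk)
foot_paths <- function(plan, times) {
  stance <- plan$init$stance
  out <- list(
    left = list(x = rep(plan$init$x - stance / 2, length(times)),
                y = rep(plan$init$y, length(times))),
    right = list(x = rep(plan$init$x + stance / 2, length(times)),
                 y = rep(plan$init$y, length(times)))
  )
  s <- plan$steps
  if (nrow(s)) for (i in seq_len(nrow(s))) {
    f <- s$foot[i]
    prof <- mj_pos((times - s$start[i]) / (s$end[i] - s$start[i]))
    out[[f]]$x <- out[[f]]$x + s$dx[i] * prof
    out[[f]]$y <- out[[f]]$y + s$dy[i] * prof
  }
  out
}

# wrist height profile: rest level, raised above head height during lifts.
# Inside a lift [s, e] the wrist follows head_z + A * sin(pi * (t-s)/(e-s)),
# so it exceeds mean head height exactly on (s, e); minimum-jerk ramps of
# length `ramp` lead in and out from/to the rest height.
wrist_z_profile <- function(times, lifts_side, rest, head_z, A, ramp) {
  z <- rep(rest, length(times))
  if (!nrow(lifts_side)) return(z)
  for (i in seq_len(nrow(lifts_side))) {
    s <- lifts_side$start[i]; e <- lifts_side$end[i]
    pre <- times >= s - ramp & times < s
    z[pre] <- rest + (head_z - rest) * mj_pos((times[pre] - (s - ramp)) / ramp)
    inside <- times >= s & times <= e
    z[inside] <- head_z + A * sin(pi * (times[inside] - s) / (e - s))
    post <- times > e & times <= e + ramp
    z[post] <- head_z + (rest - head_z) * mj_pos((times[post] - e) / ramp)
  }
  z
}

#' Render 22-marker trajectories from a movement plan
#'
#' Turns the ground-truth movement plan of [simulate_play()] into a
#' synthetic motion-capture recording at the capture rate: foot markers (toe,
#' ankle) follow their foot's commanded minimum-jerk steps and are stationary
#' otherwise; wrist markers rise above mean head height exactly during
#' commanded arm-lift intervals; the sternum and all trunk/head markers
#' follow the body's path (the avatar's lateral position plus forward
#' drift). White Gaussian noise of sd `noise_sd` is added to every
#' coordinate.
#'
#' @param plan a `movement_plan` (from [simulate_play()], or helpers such as
#'   [single_step_plan()]).
#' @param anthropometry a [default_anthropometry()] geometry.
#' @param noise_sd marker noise sd in metres (0 = noise-free; 0.002 is a
#'   realistic optical-capture figure used in the validation suite).
#' @param seed optional seed for the noise.
#' @param meta metadata list stored on the recording.
#' @return A [trial_recording()] with the full canonical marker set.
#' @export
synthesize_markers <- function(plan, anthropometry = default_anthropometry(),
                               noise_sd = 0.002, seed = NULL, meta = list()) {
  stopifnot(inherits(plan, "movement_plan"))
  a <- anthropometry
  if (a$height <= 0) stop_exerstep("ConfigError", "non-positive body height")
  rate <- plan$rate
  nfr <- max(2L, ceiling(plan$duration * rate) + 1L)
  times <- (seq_len(nfr) - 1L) / rate

  feet <- foot_paths(plan, times)
  bx <- (feet$left$x + feet$right$x) / 2
  by <- (feet$left$y + feet$right$y) / 2

  markers <- exerstep_markers()
  pos <- array(NA_real_, dim = c(nfr, length(markers), 3L),
               dimnames = list(NULL, markers, c("x", "y", "z")))
  set_m <- function(name, x, y, z) {
    pos[, name, 1] <<- x; pos[, name, 2] <<- y; pos[, name, 3] <<- z
  }

  for (s in c("L", "R")) {
    sg <- if (s == "L") -1 else 1
    f <- if (s == "L") feet$left else feet$right
    set_m(paste0("toe_", s), f$x, f$y + a$toe_dy, a$toe_z)
    set_m(paste0("ankle_", s), f$x, f$y, a$ankle_z)
    set_m(paste0("knee_", s), bx + sg * a$knee_dx, by, a$knee_z)
    set_m(paste0("head_front_", s), bx + sg * a$head_dx, by + a$head_dy, a$head_z)
    set_m(paste0("head_back_", s), bx + sg * a$head_dx, by - a$head_dy, a$head_z)
    set_m(paste0("shoulder_", s), bx + sg * a$shoulder_dx, by, a$shoulder_z)
    set_m(paste0("elbow_", s), bx + sg * a$elbow_dx, by, a$elbow_z)
    set_m(paste0("ilium_post_", s), bx + sg * a$ilium_dx, by - a$ilium_dy, a$ilium_z)
    set_m(paste0("ilium_ant_", s), bx + sg * a$ilium_dx, by + a$ilium_dy, a$ilium_z)
  }
  set_m("sternum", bx, by + a$sternum_dy, a$sternum_z)
  set_m("thigh_R", bx + a$thigh_dx, by, a$thigh_z)

  lifts <- plan$lifts
  for (s in c("left", "right")) {
    ls <- lifts[lifts$side %in% c(s, "both"), , drop = FALSE]
    wz <- wrist_z_profile(times, ls, a$wrist_z, a$head_z,
                          a$lift_amplitude, a$lift_ramp)
    sg <- if (s == "left") -1 else 1
    nm <- paste0("wrist_", if (s == "left") "L" else "R")
    set_m(nm, bx + sg * a$wrist_dx, by, wz)
  }

  if (noise_sd > 0) {
    with_seed(seed, pos <- pos + rnorm(length(pos), 0, noise_sd))
  }
  trial_recording(pos, rate = rate, meta = meta)
}

#' Ground-truth events of a simulated trial
#'
#' Converts the commanded movement plan into the events an ideal
#' velocity-threshold detector would report: each commanded minimum-jerk step
#' contributes the interval on which its ideal speed profile exceeds the
#' stationary band (and the displacement accumulated inside it), arm lifts
#' keep their commanded above-head interval, and single-support intervals are
#' derived from the thresholded step intervals.
#'
#' @param sim an `exergame_sim` from [simulate_play()] (or a bare
#'   `movement_plan`).
#' @param stationary_speed velocity band used for the threshold-equivalent
#'   boundaries, m/s.
#' @return List of class `ground_truth`: `steps` (per-foot data frames with
#'   `start`, `end`, `size`), `commanded_steps`, `lifts`, `support`,
#'   `errors`, `duration`.
#' @export
ground_truth <- function(sim, stationary_speed = 0.1) {
  plan <- if (inherits(sim, "movement_plan")) sim else sim$plan
  s <- plan$steps
  per_foot <- list(left = empty_steps()[, -1], right = empty_steps()[, -1])
  if (nrow(s)) {
    rows <- lapply(seq_len(nrow(s)), function(i) {
      disp <- sqrt(s$dx[i]^2 + s$dy[i]^2)
      iv <- mj_threshold_interval(s$start[i], s$end[i] - s$start[i], disp,
                                  stationary_speed)
      if (is.null(iv)) return(NULL)
      data.frame(foot = s$foot[i], start = iv$start, end = iv$end, size = iv$size)
    })
    all <- do.call(rbind, rows)
    if (!is.null(all)) {
      for (f in c("left", "right")) {
        d <- all[all$foot == f, c("start", "end", "size"), drop = FALSE]
        rownames(d) <- NULL
        per_foot[[f]] <- d[order(d$start), , drop = FALSE]
      }
    }
  }
  structure(list(
    steps = per_foot,
    commanded_steps = s,
    lifts = plan$lifts,
    support = derive_single_support(per_foot, plan$duration),
    errors = plan$errors,
    duration = plan$duration
  ), class = "ground_truth")
}

#' Hand-built movement plans
#'
#' Small constructors used in examples and validation: an empty plan (a
#' standing player) and a plan containing exactly one step and optionally one
#' arm lift.
#'
#' @param duration recording duration, s.
#' @param rate sampling rate, Hz.
#' @return A `movement_plan`.
#' @export
empty_movement_plan <- function(duration = 2, rate = 120) {
  structure(list(
    duration = duration, game_duration = duration, rate = rate,
    init = list(x = 0, y = -0.5, stance = 0.25),
    steps = bind_rows_list(list(), c("foot", "start", "end", "dx", "dy")),
    lifts = bind_rows_list(list(), c("side", "start", "end")),
    errors = bind_rows_list(list(), c("start", "duration", "direction"))
  ), class = "movement_plan")
}

#' @rdname empty_movement_plan
#' @param foot stepping foot.
#' @param size step displacement, m (lateral).
#' @param start,step_duration timing of the step, s.
#' @param lift optional arm-lift side (`"left"`, `"right"`, `"both"`) to add
#'   after the step; `NULL` for none.
#' @export
single_step_plan <- function(foot = "right", size = 0.25, start = 0.5,
                             step_duration = 0.4, duration = 3, rate = 120,
                             lift = NULL) {
  plan <- empty_movement_plan(duration, rate)
  plan$steps <- data.frame(foot = foot, start = start,
                           end = start + step_duration, dx = size, dy = 0)
  if (!is.null(lift)) {
    plan$lifts <- data.frame(side = lift, start = min(duration - 1.2, start + 1),
                             end = min(duration - 0.2, start + 2))
  }
  plan
}
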