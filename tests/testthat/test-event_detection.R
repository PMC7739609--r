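test_that("estimate_speed matches analytic derivatives", {
  rate <- 120
  t <- seq(0, 2, by = 1 / rate)
  # constant position -> zero speed
  expect_lt(max(estimate_speed(cbind(rep(0.3, length(t)), -0.2, 1), rate = rate)),
            1e-4)
  # uniform motion along X at 0.5 m/s
  s <- estimate_speed(cbind(0.5 * t, 0, 0), rate = rate, cutoff = 6)
  interior <- seq(20, length(t) - 20)
  expect_equal(s[interior], rep(0.5, length(interior)), tolerance = 1e-3)
  # 1 Hz sinusoid, amplitude 0.1 m: |v| = 0.2*pi*|cos(2*pi*t)|
  x <- 0.1 * sin(2 * pi * t)
  s2 <- estimate_speed(cbind(x, 0, 0), rate = rate, cutoff = 20)
  expect_equal(s2[interior], 0.2 * pi * abs(cos(2 * pi * t[interior])),
               tolerance = 0.01 * 0.2 * pi)
  expect_error(estimate_speed(matrix(0, 2, 3), rate),
               class = "exerstep_InsufficientData")
  expect_error(estimate_speed(cbind(t, t, t), rate, cutoff = 80),
               class = "exerstep_ConfigError")
})

test_that("sub-threshold bursts are rejected, compliant bursts accepted", {
  rate <- 120
  cfg <- detection_config(filter_cutoff = NA)
  burst <- function(d, dur) {
    nfr <- round(dur * rate)
    x <- c(rep(0, 60), d * exerstep:::mj_pos(seq_len(nfr) / nfr), rep(d, 60))
    cbind(x, 0, 0)
  }
  # displacement below 0.03 m -> rejected
  expect_equal(nrow(exerstep:::detect_steps_one(burst(0.02, 0.2), rate, cfg)), 0L)
  # burst lasting ~0.03 s -> rejected (even though fast enough to cross band)
  expect_equal(nrow(exerstep:::detect_steps_one(burst(0.05, 0.03), rate, cfg)), 0L)
  # minimally compliant: slightly above both thresholds -> exactly one step
  s <- exerstep:::detect_steps_one(burst(0.035, 0.25), rate, cfg)
  expect_equal(nrow(s), 1L)
  expect_gte(s$size, 0.03)
  expect_gte(s$end - s$start, 0.05)
  # static -> nothing
  expect_equal(nrow(exerstep:::detect_steps_one(cbind(rep(0, 200), 0, 0), rate, cfg)), 0L)
})

test_that("a padded minimum-jerk move yields one step matching the scan oracle", {
  rate <- 120
  cfg <- detection_config(filter_cutoff = NA)
  nfr <- round(0.4 * rate)
  x <- c(rep(0, 60), 0.25 * exerstep:::mj_pos(seq_len(nfr) / nfr), rep(0.25, 60))
  xyz <- cbind(x, 0, 0)
  det <- exerstep:::detect_steps_one(xyz, rate, cfg)
  orc <- oracle_step_scan(xyz, rate, cfg)
  expect_equal(nrow(det), 1L)
  expect_equal(det$start, orc$start, tolerance = 1 / rate)
  expect_equal(det$end, orc$end, tolerance = 1 / rate)
  expect_equal(det$size, orc$size, tolerance = 1e-9)
  # and the boundaries sit near the analytic threshold crossings
  iv <- exerstep:::mj_threshold_interval(60 / rate, 0.4, 0.25, 0.1)
  expect_lt(abs(det$start - iv$start), 1.5 / rate)
  expect_lt(abs(det$end - iv$end), 1.5 / rate)
})

test_that("detect_steps equals the exhaustive threshold scan on random series", {
  cfg <- detection_config(filter_cutoff = NA)
  cfg_f <- detection_config()
  set.seed(42)
  for (k in 1:60) {
    tr <- random_burst_trajectory(n_moves = sample(2:6, 1),
                                  noise = sample(c(0, 0.002), 1))
    use <- if (k %% 2) cfg else cfg_f
    det <- exerstep:::detect_steps_one(tr$xyz, 120, use)
    orc <- oracle_step_scan(tr$xyz, 120, use)
    expect_equal(nrow(det), nrow(orc))
    if (nrow(det)) {
      expect_equal(det$start, orc$start)
      expect_equal(det$end, orc$end)
      expect_equal(det$size, orc$size)
    }
  }
})

test_that("raising thresholds never increases the step count", {
  set.seed(7)
  for (k in 1:10) {
    tr <- random_burst_trajectory(n_moves = 5, noise = 0.002)
    base <- nrow(exerstep:::detect_steps_one(tr$xyz, 120, detection_config()))
    for (md in c(0.05, 0.1)) {
      n <- nrow(exerstep:::detect_steps_one(
        tr$xyz, 120, detection_config(min_displacement = md)))
      expect_lte(n, base)
    }
    for (dur in c(0.15, 0.3)) {
      n <- nrow(exerstep:::detect_steps_one(
        tr$xyz, 120, detection_config(min_duration = dur)))
      expect_lte(n, base)
    }
  }
})

test_that("step detection is invariant to translation and rotation about Z", {
  set.seed(9)
  tr <- random_burst_trajectory(n_moves = 4, noise = 0.001)
  cfg <- detection_config()
  base <- exerstep:::detect_steps_one(tr$xyz, 120, cfg)
  shifted <- sweep(tr$xyz, 2, c(3.2, -1.5, 0.7), "+")
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  rotated <- tr$xyz %*% t(R)
  for (other in list(shifted, rotated)) {
    d <- exerstep:::detect_steps_one(other, 120, cfg)
    expect_equal(nrow(d), nrow(base))
    expect_equal(d$size, base$size, tolerance = 1e-8)
    expect_equal(d$start, base$start)
  }
})

test_that("detect_steps requires the configured foot markers", {
  rec <- recording_with("sternum", cbind(rep(0, 200), 0, 0))
  expect_error(detect_steps(rec), class = "exerstep_MarkerSetMismatch")
})

test_that("arm lifts follow the head-height crossing rule", {
  rate <- 120
  n <- 600
  heads <- paste0(rep(c("head_front", "head_back"), each = 2), c("_L", "_R"))
  mk <- c(heads, "wrist_L", "wrist_R")
  pos <- array(0, dim = c(n, length(mk), 3), dimnames = list(NULL, mk, NULL))
  pos[, heads, 3] <- 1.6
  pos[, "wrist_L", 3] <- 0.9
  pos[, "wrist_R", 3] <- 0.9
  # wrist below head for the whole trial -> no events
  rec <- trial_recording(pos, rate)
  expect_equal(nrow(detect_arm_lifts(rec)), 0L)

  # one square-wave excursion -> one event with boundaries at the crossings
  pos[200:320, "wrist_R", 3] <- 1.8
  rec <- trial_recording(pos, rate)
  ev <- detect_arm_lifts(rec)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$side, "right")
  expect_equal(ev$start, 199 / rate)
  expect_equal(ev$end, 320 / rate)

  # two separated excursions -> two events, agreeing with the crossing scan
  pos[450:520, "wrist_R", 3] <- 1.75
  rec <- trial_recording(pos, rate)
  ev2 <- detect_arm_lifts(rec)
  orc <- oracle_lift_scan(pos[, "wrist_R", 3], rep(1.6, n), rate)
  expect_equal(nrow(ev2), 2L)
  expect_equal(ev2$start, orc$start)
  expect_equal(ev2$end, orc$end)

  # chatter shorter than min_lift_duration is discarded
  pos2 <- pos
  pos2[, "wrist_R", 3] <- 0.9
  pos2[100:105, "wrist_R", 3] <- 1.65
  expect_equal(nrow(detect_arm_lifts(trial_recording(pos2, rate))), 0L)

  # simultaneous bilateral excursions merge to side = "both"
  pos3 <- pos
  pos3[, "wrist_R", 3] <- 0.9
  pos3[250:350, "wrist_L", 3] <- 1.8
  pos3[260:340, "wrist_R", 3] <- 1.8
  ev3 <- detect_arm_lifts(trial_recording(pos3, rate))
  expect_equal(ev3$side, "both")
  missing_head <- trial_recording(pos[, c("wrist_L", "wrist_R"), , drop = FALSE], rate)
  expect_error(detect_arm_lifts(missing_head), class = "exerstep_MarkerSetMismatch")
})

test_that("single-support intervals follow the interval arithmetic", {
  none <- list(left = data.frame(start = numeric(), end = numeric(), size = numeric()),
               right = data.frame(start = numeric(), end = numeric(), size = numeric()))
  ss0 <- derive_single_support(none, duration = 120)
  expect_equal(nrow(ss0$left) + nrow(ss0$right), 0L)

  # one right step, left quiet: left stance supports for 0.5 s
  steps <- none
  steps$right <- data.frame(start = 2.0, end = 2.5, size = 0.2)
  ss <- derive_single_support(steps, 120)
  expect_equal(unname(ss$left[1, ]), c(2.0, 2.5))
  expect_equal(nrow(ss$right), 0L)

  # overlapping swings: the 2.4-2.5 double-swing is excluded from both
  steps$left <- data.frame(start = 2.4, end = 2.9, size = 0.2)
  ss2 <- derive_single_support(steps, 120)
  expect_equal(unname(ss2$left[1, ]), c(2.0, 2.4))
  expect_equal(unname(ss2$right[1, ]), c(2.5, 2.9))
  # ... unless exclusion is turned off
  ss3 <- derive_single_support(steps, 120, exclude_double_swing = FALSE)
  expect_equal(unname(ss3$left[1, ]), c(2.0, 2.5))

  # intervals are clipped to the recording
  steps$right <- data.frame(start = -1, end = 0.5, size = 0.2)
  steps$left <- none$left
  ss4 <- derive_single_support(steps, duration = 0.4)
  expect_equal(unname(ss4$left[1, ]), c(0, 0.4))
})
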