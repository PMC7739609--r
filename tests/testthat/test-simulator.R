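test_that("schedules respect concurrency, chicken count and fall-time ranges", {
  for (sp in c("low", "high")) {
    s <- game_settings(sp, "with")
    sched <- generate_object_schedule(s, seed = 100 + (sp == "high"))
    expect_equal(sum(sched$kind == "chicken"), 11L)
    # chicken windows are disjoint and inside the trial
    ch <- sched[sched$kind == "chicken", ]
    ch <- ch[order(ch$spawn_time), ]
    expect_true(all(diff(ch$spawn_time) >= s$chicken_window - 1e-9))
    expect_true(all(ch$spawn_time >= 0 & ch$arrival <= s$trial_duration + 1e-9))
    for (kind in c("grape", "branch")) {
      conc <- if (kind == "grape") s$grape_concurrency else s$branch_concurrency
      cc <- exerstep:::schedule_concurrency(sched, kind)
      expect_true(all(cc$count >= conc[1] & cc$count <= conc[2]))
      ft <- sched$fall_time[sched$kind == kind]
      expect_true(all(ft >= s$fall_time_range[1] & ft <= s$fall_time_range[2]))
    }
    # branches stay within the play area
    br <- sched[sched$kind == "branch", ]
    expect_true(all(br$lo >= -1 & br$hi <= 1))
  }
  # no branches without obstacles
  s0 <- generate_object_schedule(game_settings("low", "without"), seed = 5)
  expect_false(any(s0$kind == "branch"))
  expect_error(
    generate_object_schedule(game_settings(trial_duration = 0), seed = 1),
    class = "exerstep_ScheduleInfeasible")
  expect_error(
    generate_object_schedule(game_settings(trial_duration = 60), seed = 1),
    class = "exerstep_ScheduleInfeasible")  # 11 x 7 s does not fit
})

test_that("simulation is deterministic under the seed", {
  s <- game_settings("high", "with")
  a <- generate_object_schedule(s, seed = 9)
  b <- generate_object_schedule(s, seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  sa <- simulate_play(a, player_policy(), seed = 21)
  sb <- simulate_play(b, player_policy(), seed = 21)
  expect_identical(sa$plan$steps, sb$plan$steps)
  expect_identical(sa$log$objects$outcome, sb$log$objects$outcome)
  expect_identical(sa$log$score, sb$log$score)
  ra <- synthesize_markers(sa$plan, seed = 3)
  rb <- synthesize_markers(sb$plan, seed = 3)
  expect_identical(ra$positions, rb$positions)
})

test_that("every presented object is resolved and the score identity holds", {
  for (seed in 1:5) {
    cond <- if (seed %% 2) c("low", "with") else c("high", "without")
    s <- game_settings(cond[1], cond[2])
    sched <- generate_object_schedule(s, seed = seed)
    sim <- simulate_play(sched, player_policy(), seed = seed)
    o <- sim$log$objects
    resolved <- o[o$outcome != "pending", ]
    expect_true(all(o$arrival[o$outcome == "pending"] >
                      s$trial_duration - 1e-9))
    expect_true(all(resolved$outcome[resolved$kind == "grape"] %in%
                      c("caught", "missed")))
    expect_true(all(resolved$outcome[resolved$kind == "branch"] %in%
                      c("hit", "avoided")))
    sc <- score_trial(sim$log)
    expect_identical(sim$log$score, sc$score)
    expect_identical(sc$score,
                     as.integer(sc$grapes[["caught"]] + 3 * sc$chickens[["caught"]] -
                                  2 * sc$branches[["hit"]]))
    # clock accounting: active + pauses = recording
    d <- sim$log$durations
    expect_equal(d$active + d$pauses, d$recording, tolerance = 1e-9)
  }
})

test_that("arm policies shape chicken outcomes", {
  s <- game_settings("low", "without")
  sched <- generate_object_schedule(s, seed = 2)
  never <- simulate_play(sched, player_policy(arm_style = "never"), seed = 2)
  expect_equal(score_trial(never$log)$chickens[["caught"]], 0)
  expect_equal(nrow(never$plan$lifts), 0L)
  always <- simulate_play(sched, player_policy(arm_lift_probability = 1), seed = 2)
  expect_gt(score_trial(always$log)$chickens[["caught"]], 5)
})

test_that("a parked avatar catches a hand-scripted single grape", {
  s <- game_settings("low", "without", trial_duration = 10, chickens_per_trial = 0)
  sched <- structure(
    data.frame(kind = "grape", spawn_time = 1, fall_time = 8, arrival = 9,
               x = 0, lo = NA_real_, hi = NA_real_, outcome = "pending"),
    settings = s, class = c("game_schedule", "data.frame"))
  sim <- simulate_play(sched, player_policy(), seed = 1)
  expect_equal(sim$log$objects$outcome, "caught")
  expect_equal(sim$log$score, 1L)
  # and an out-of-reach grape is missed
  sched2 <- sched
  sched2$x <- 0.9
  sched2$fall_time <- 0.5
  sched2$arrival <- 1.5
  sim2 <- simulate_play(sched2, player_policy(reaction_delay = 2), seed = 1)
  expect_equal(sim2$log$objects$outcome, "missed")
})

test_that("synthesized markers realize the commanded plan exactly", {
  # empty plan, no noise: everything static
  rec0 <- synthesize_markers(empty_movement_plan(1), noise_sd = 0)
  expect_true(all(apply(rec0$positions, c(2, 3), function(v) diff(range(v))) == 0))

  # one 0.25 m step: the toe marker moves exactly that much, ankle with it
  rec1 <- synthesize_markers(single_step_plan(foot = "right", size = 0.25),
                             noise_sd = 0)
  toe <- marker_xyz(rec1, "toe_R")
  expect_equal(unname(toe[nrow(toe), 1] - toe[1, 1]), 0.25, tolerance = 1e-9)
  expect_equal(max(abs(diff(marker_xyz(rec1, "toe_L")[, 1]))), 0)
  ank <- marker_xyz(rec1, "ankle_R")
  expect_equal(unname(ank[nrow(ank), 1] - ank[1, 1]), 0.25, tolerance = 1e-9)

  # one arm lift: wrist exceeds mean head height exactly during the interval
  plan <- single_step_plan(lift = "left", duration = 4)
  rec2 <- synthesize_markers(plan, noise_sd = 0)
  t <- exerstep:::rec_times(rec2)
  heads <- paste0(rep(c("head_front", "head_back"), each = 2), c("_L", "_R"))
  hz <- rowMeans(sapply(heads, function(m) marker_xyz(rec2, m)[, 3]))
  wz <- marker_xyz(rec2, "wrist_L")[, 3]
  above <- wz > hz
  inside <- t > plan$lifts$start & t < plan$lifts$end
  expect_equal(above, inside)

  expect_error(synthesize_markers(single_step_plan(),
                                  anthropometry = default_anthropometry(-1)),
               class = "exerstep_ConfigError")
})

test_that("noise-free detection recovers the ground truth exactly", {
  cfg <- detection_config(filter_cutoff = NA, lift_hysteresis = 0)
  for (seed in c(3, 17)) {
    s <- game_settings(if (seed == 3) "low" else "high", "with")
    sched <- generate_object_schedule(s, seed = seed)
    sim <- simulate_play(sched, player_policy(), seed = seed)
    rec <- synthesize_markers(sim$plan, noise_sd = 0)
    gt <- ground_truth(sim)
    det <- detect_steps(rec, cfg)
    for (f in c("left", "right")) {
      expect_equal(nrow(det[[f]]), nrow(gt$steps[[f]]))
      # boundaries within one frame of the analytic threshold crossings
      expect_lt(max(abs(det[[f]]$start - gt$steps[[f]]$start)), 1.01 / 120)
      expect_lt(max(abs(det[[f]]$end - gt$steps[[f]]$end)), 1.01 / 120)
      expect_lt(max(abs(det[[f]]$size - gt$steps[[f]]$size)), 0.005)
    }
    lifts <- detect_arm_lifts(rec, cfg)
    expect_equal(nrow(lifts), nrow(gt$lifts))
    # single-support totals match within frame quantization
    sup <- derive_single_support(det, rec$duration)
    tot <- function(ss) sum(ss[, 2] - ss[, 1])
    n_steps <- nrow(det$left) + nrow(det$right)
    for (f in c("left", "right")) {
      expect_lt(abs(tot(sup[[f]]) - tot(gt$support[[f]])), 2 * n_steps / 120)
    }
  }
})

test_that("cohorts implement the counterbalanced 4 x 2 design", {
  expect_length(make_cohort(0, seed = 1), 0L)
  coh <- make_cohort(4, seed = 1, render = FALSE,
                     settings_overrides = quick_cohort_overrides)
  expect_length(coh, 32L)  # 4 participants x 8 trials
  meta <- do.call(rbind, lapply(coh, function(e)
    data.frame(e$meta[c("participant", "gender", "speed", "obstacles",
                        "repetition", "trial_index")])))
  # each condition exactly twice per participant
  tab <- table(meta$participant, paste(meta$speed, meta$obstacles))
  expect_true(all(tab == 2L))
  # counterbalancing: each condition appears once per serial position
  # within each block across a full Latin-square rotation of participants
  first_block <- meta[meta$trial_index <= 4, ]
  pos_tab <- table(first_block$trial_index,
                   paste(first_block$speed, first_block$obstacles))
  expect_true(all(pos_tab == 1L))
  # 15 participants -> 120 trials, gender split 7/8
  coh15 <- make_cohort(15, seed = 2, render = FALSE,
                       settings_overrides = quick_cohort_overrides)
  expect_length(coh15, 120L)
  g <- vapply(coh15, function(e) e$meta$gender, "")
  expect_equal(sum(tapply(g, vapply(coh15, function(e) e$meta$participant, ""),
                          function(x) x[1]) == "female"), 7L)
})

test_that("recordings produced by the cohort round-trip through files", {
  coh <- make_cohort(1, seed = 3, render = TRUE, noise_sd = 0.002,
                     settings_overrides = quick_cohort_overrides)
  rec <- coh[[1]]$recording
  expect_s3_class(rec, "trial_recording")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, f, units = "mm")
  rec2 <- load_recording(f)
  expect_equal(rec2$positions, rec$positions, tolerance = 1e-5)
})
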