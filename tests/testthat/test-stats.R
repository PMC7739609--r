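cohort_metrics_table <- function(n = 3, seed = 5) {
  coh <- make_cohort(n, seed = seed, render = FALSE,
                     settings_overrides = quick_cohort_overrides)
  mets <- lapply(coh, function(e) {
    # metrics straight from ground truth (no rendering needed here)
    gt <- e$truth
    dur <- gt$duration
    per_foot <- merge(step_metrics(gt$steps, dur),
                      support_metrics(gt$support, dur), by = "foot")
    structure(list(per_foot = per_foot,
                   arm_lifts = arm_lift_frequency(gt$lifts, dur),
                   anterior_drift = 0.1, trial_time = dur, meta = e$meta),
              class = "trial_metrics")
  })
  assemble_metrics_table(mets)
}

test_that("the metrics table is long-format with declared factor columns", {
  expect_equal(nrow(assemble_metrics_table(list())), 0L)
  tab <- cohort_metrics_table(3)
  # 3 participants x 8 trials x (2 sides x 5 metrics + 1 trial-level)
  expect_equal(nrow(tab), 3 * 8 * 11)
  expect_equal(sum(tab$metric == "cadence"), 3 * 8 * 2)
  expect_setequal(setdiff(names(tab), c("participant", "metric", "value")),
                  c("gender", "speed", "obstacles", "repetition", "side"))
  dup <- rbind(tab, tab[1, ])
  expect_error(assemble_metrics_table(list()) -> ok, NA)
  mets <- list(structure(list(per_foot = merge(
    step_metrics(list(left = data.frame(start = 1, end = 2, size = 0.1),
                      right = data.frame(start = numeric(), end = numeric(),
                                         size = numeric())), 10),
    support_metrics(list(left = cbind(start = 1, end = 2),
                         right = cbind(start = numeric(), end = numeric())), 10),
    by = "foot"),
    arm_lifts = c(left = 0, right = 0, combined = 0),
    anterior_drift = 0, trial_time = 10,
    meta = list(participant = "P01", gender = "female", speed = "low",
                obstacles = "without", repetition = 1)), class = "trial_metrics"))
  expect_error(assemble_metrics_table(c(mets, mets)),
               class = "exerstep_DuplicateRow")
})

test_that("with no variance components the fit collapses to least squares", {
  cfg <- recovery_config(sd_intercept = 0, sd_side = 0, sigma = 1e-6)
  tab <- simulate_lmm_metrics(cfg, seed = 2)
  fit <- suppressWarnings(fit_lmm(tab, lmm_spec("cadence")))
  ols <- stats::lm(value ~ speed + obstacles + repetition + gender + side,
                   data = exerstep:::code_factors(tab))
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-6)
  expect_equal(fit$coefficients$estimate[2], 6.89, tolerance = 1e-4)
})

test_that("effect tests cover exactly the five design factors", {
  tab <- simulate_lmm_metrics(seed = 3)
  fit <- suppressWarnings(fit_lmm(tab, lmm_spec("cadence")))
  et <- effect_tests(fit)
  expect_setequal(et$effect, c("speed", "obstacles", "repetition", "gender", "side"))
  expect_true(all(et$df1 == 1))
  expect_equal(et$statistic, fit$coefficients$t[-1]^2)
  # gender is a between-participant effect: far fewer denominator df
  expect_lt(et$df2[et$effect == "gender"], 20)
  expect_gt(min(et$df2[et$effect != "gender"]), 200)
  # a huge injected speed effect is detected
  expect_lt(et$p[et$effect == "speed"], 1e-10)
  bad <- fit; bad$converged <- FALSE
  expect_error(effect_tests(bad), class = "exerstep_TestUnavailable")
})

test_that("variance components are recovered in the designed direction", {
  # participant-constant responses: residual variance ~ 0
  cfg <- recovery_config(sd_intercept = 4, sd_side = 0, sigma = 1e-4,
                         effects = c(speed = 0, obstacles = 0, repetition = 0,
                                     gender = 0, side = 0))
  tab <- simulate_lmm_metrics(cfg, seed = 7)
  fit <- suppressWarnings(fit_lmm(tab, lmm_spec("cadence",
                                                random = "intercept")))
  vc <- fit$varcomp
  resid_sd <- vc$sdcor[vc$grp == "Residual"]
  int_sd <- vc$sdcor[vc$grp == "participant" & vc$var1 == "(Intercept)"]
  expect_lt(resid_sd, 0.01)
  expect_gt(int_sd, 2)

  # intraclass correlation ~ 0.5 when intercept and residual variance match
  cfg2 <- recovery_config(sd_intercept = 5, sd_side = 0, sigma = 5,
                          effects = c(speed = 0, obstacles = 0, repetition = 0,
                                      gender = 0, side = 0))
  iccs <- vapply(1:20, function(k) {
    tab <- simulate_lmm_metrics(cfg2, seed = 100 + k)
    fit <- suppressWarnings(fit_lmm(tab, lmm_spec("cadence", random = "intercept")))
    vc <- fit$varcomp
    v_int <- vc$vcov[vc$grp == "participant" & vc$var1 == "(Intercept)"]
    v_res <- vc$vcov[vc$grp == "Residual"]
    v_int / (v_int + v_res)
  }, 0)
  expect_equal(mean(iccs), 0.5, tolerance = 0.1)
})

test_that("the fit is invariant to row order and drops missing rows", {
  tab <- simulate_lmm_metrics(seed = 9)
  fit1 <- suppressWarnings(fit_lmm(tab, lmm_spec("cadence")))
  set.seed(1)
  fit2 <- suppressWarnings(fit_lmm(tab[sample(nrow(tab)), ], lmm_spec("cadence")))
  expect_equal(fit1$coefficients$estimate, fit2$coefficients$estimate,
               tolerance = 1e-6)

  tab$value[c(3, 17, 40)] <- NA
  fit3 <- suppressWarnings(fit_lmm(tab, lmm_spec("cadence")))
  expect_equal(fit3$n_dropped, 3L)
  expect_equal(fit3$n_obs, nrow(tab) - 3L)

  expect_error(fit_lmm(tab, lmm_spec("nope")), class = "exerstep_ConfigError")
  one <- tab[tab$participant == "P01", ]
  expect_error(fit_lmm(one, lmm_spec("cadence")), class = "exerstep_ConfigError")
})

test_that("recovery experiments are unbiased at zero effects and shrink with n", {
  null_cfg <- recovery_config(effects = c(speed = 0, obstacles = 0,
                                          repetition = 0, gender = 0, side = 0))
  rep0 <- recovery_experiment(null_cfg, n_reps = 30, seed = 21)
  # mean estimates within Monte-Carlo error of zero
  mc_se <- apply(rep0$estimates, 2, sd) / sqrt(rep0$n_reps)
  expect_true(all(abs(rep0$summary$mean_estimate) < 4 * mc_se + 1e-9))

  big <- recovery_config(n_participants = 30)
  small_r <- recovery_experiment(recovery_config(), n_reps = 25, seed = 22)
  big_r <- recovery_experiment(big, n_reps = 25, seed = 23)
  expect_lt(mean(big_r$summary$rmse), mean(small_r$summary$rmse))
  expect_error(recovery_experiment(n_reps = 0), class = "exerstep_ConfigError")
})

test_that("pooled group means reproduce the weighted arithmetic", {
  expect_equal(round(pooled_group_mean(c(166.8, 175.2), c(7, 8)), 1), 171.3)
  expect_equal(round(pooled_group_mean(c(65.4, 76.0), c(7, 8)), 2), 71.05)
  expect_equal(pooled_group_mean(c(4.2, 4.2, 4.2), c(1, 5, 9)), 4.2)
  expect_error(pooled_group_mean(numeric(), numeric()),
               class = "exerstep_UndefinedMean")
  expect_error(pooled_group_mean(c(1, 2), c(3, 0)), class = "exerstep_ConfigError")
})

test_that("injected effects are recovered with the right sign", {
  r <- recovery_experiment(n_reps = 25, seed = 41)
  signs <- sign(r$estimates)
  truth_sign <- sign(r$config$effects)
  # the two large effects (speed, obstacles) agree in sign in >= 95% of reps
  for (f in c("speed", "obstacles")) {
    expect_gte(mean(signs[, f] == truth_sign[[f]]), 0.95)
  }
})

test_that("the full simulate->metrics->fit chain shows the study's directions", {
  # obstacles slow the player down (waiting for branches) and suppress arm
  # lifts; higher speed raises the score. Fitted on ground-truth metrics at
  # the full trial length (the waiting behaviour needs realistic fall times).
  coh <- make_cohort(4, seed = 31, render = FALSE)
  mets <- lapply(coh, function(e) {
    gt <- e$truth
    structure(list(per_foot = merge(step_metrics(gt$steps, gt$duration),
                                    support_metrics(gt$support, gt$duration),
                                    by = "foot"),
                   arm_lifts = arm_lift_frequency(gt$lifts, gt$duration),
                   anterior_drift = 0.1, trial_time = gt$duration,
                   meta = e$meta), class = "trial_metrics")
  })
  tab <- assemble_metrics_table(mets)
  for (resp in c("cadence", "arm_lift_frequency")) {
    fit <- suppressWarnings(fit_lmm(tab, lmm_spec(resp)))
    co <- fit$coefficients
    expect_lt(co$estimate[co$effect %in% "obstacles"], 0)
  }
  sc <- vapply(coh, function(e) as.numeric(e$sim$log$score), 0)
  sp <- vapply(coh, function(e) e$meta$speed, "")
  ob <- vapply(coh, function(e) e$meta$obstacles, "")
  expect_gt(mean(sc[sp == "high"]), mean(sc[sp == "low"]))
  expect_lt(mean(sc[ob == "with"]), mean(sc[ob == "without"]))
})
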