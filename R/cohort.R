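# Study-design replica: each participant plays 8 two-minute trials, the four
# speed x obstacle conditions twice each, in an order counterbalanced across
# participants (rows of a 4 x 4 Latin square; the second block reverses the
# first, so every condition appears once early and once late).

condition_grid <- function() {
  data.frame(speed = rep(c("low", "high"), each = 2),
             obstacles = rep(c("without", "with"), 2))
}

latin_square_4 <- function() {
  # cyclic 4 x 4 square
  t(vapply(0:3, function(r) (r + 0:3) %% 4L + 1L, integer(4)))
}

trial_sequence <- function(participant_index) {
  row <- latin_square_4()[(participant_index - 1L) %% 4L + 1L, ]
  c(row, rev(row))  # block 1 then mirrored block 2
}

derive_seed <- function(seed, ...) {
  k <- c(...)
  as.integer((sum(as.numeric(seed) * 7919 + cumsum(as.numeric(k) * 104729)) +
                as.numeric(seed)) %% 2147480017)
}

#' Simulate a cohort of exergame players
#'
#' Draws one behaviour policy per participant (the between-participant
#' variation the mixed model's random intercept captures), assigns gender
#' (7 female / 8 male at the study's n = 15; proportionally otherwise),
#' counterbalances condition order with a Latin square, and simulates all
#' 8 trials per participant, optionally rendering marker trajectories.
#'
#' @param n_participants number of participants (>= 0).
#' @param seed integer master seed; every trial seed derives from it.
#' @param policy_population function returning a policy-drawing function, see
#'   [default_policy_population()].
#' @param settings_overrides named list passed on to [game_settings()]
#'   (e.g. `list(trial_duration = 30)` for quick experiments; note chickens
#'   scale with nothing -- shorten `chickens_per_trial` along with the
#'   duration).
#' @param render if `TRUE` (default) synthesize marker recordings; if
#'   `FALSE` only plans and logs are produced (much faster).
#' @param noise_sd marker noise passed to [synthesize_markers()].
#' @return List of class `exergame_cohort`: one element per trial with
#'   `recording` (or `NULL`), `sim` (the `exergame_sim`), `truth`
#'   ([ground_truth()]) and `meta`.
#' @export
#' @examples
#' coh <- make_cohort(2, seed = 1, render = FALSE,
#'                    settings_overrides = list(trial_duration = 30,
#'                                              chickens_per_trial = 3))
#' length(coh)  # 2 participants x 8 trials
make_cohort <- function(n_participants, seed,
                        policy_population = default_policy_population(),
                        settings_overrides = list(),
                        render = TRUE, noise_sd = 0.002) {
  if (n_participants < 0) stop_exerstep("ConfigError", "n_participants must be >= 0")
  if (n_participants == 0) return(structure(list(), class = "exergame_cohort"))
  n_female <- round(n_participants * 7 / 15)
  genders <- rep(c("female", "male"),
                 c(n_female, n_participants - n_female))
  grid <- condition_grid()
  out <- list()
  for (p in seq_len(n_participants)) {
    policy <- with_seed(derive_seed(seed, p, 0), policy_population())
    seqn <- trial_sequence(p)
    for (tr in seq_along(seqn)) {
      cond <- grid[seqn[tr], ]
      rep_no <- if (tr <= 4L) 1L else 2L
      so <- modifyList(list(speed = cond$speed, obstacles = cond$obstacles),
                       settings_overrides)
      settings <- do.call(game_settings, so)
      tseed <- derive_seed(seed, p, tr)
      sched <- generate_object_schedule(settings, seed = tseed)
      sim <- simulate_play(sched, policy, settings, seed = tseed + 1L)
      meta <- list(participant = sprintf("P%02d", p), gender = genders[p],
                   speed = cond$speed, obstacles = cond$obstacles,
                   repetition = rep_no, trial_index = tr)
      sim$log$meta <- modifyList(sim$log$meta, meta)
      rec <- if (render) {
        synthesize_markers(sim$plan, noise_sd = noise_sd,
                           seed = tseed + 2L, meta = meta)
      }
      out[[length(out) + 1L]] <- list(recording = rec, sim = sim,
                                      truth = ground_truth(sim), meta = meta)
    }
  }
  structure(out, class = "exergame_cohort")
}

#' @export
print.exergame_cohort <- function(x, ...) {
  np <- length(unique(vapply(x, function(e) e$meta$participant, "")))
  cat(sprintf("<exergame_cohort> %d trials from %d participants\n", length(x), np))
  invisible(x)
}
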