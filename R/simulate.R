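#' Simulate a player completing one trial
#'
#' Plays a scheduled trial with a behaviour model, producing the commanded
#' movement plan (ground truth), the structured game event log, and the
#' avatar trajectory. The avatar mirrors the body's lateral position, which
#' moves through discrete side steps: a lead step in the movement direction
#' followed by a trailing step of the other foot, each a minimum-jerk
#' profile. Grapes are caught iff the avatar is within
#' `catch_half_width` of the grape at its arrival; a branch hits iff the
#' avatar is inside the branch interval at arrival; a chicken is caught iff
#' an arm lift happens under it inside its window. Whenever the trunk leaves
#' the active area the game clock pauses, an error message is logged, and the
#' player steps back in; the motion-capture clock keeps running, so the
#' recording is longer than the active game time.
#'
#' @param schedule a [generate_object_schedule()] result.
#' @param policy a [player_policy()].
#' @param settings the [game_settings()] of the schedule (defaults to the
#'   schedule's own).
#' @param seed integer seed for the behavioural randomness.
#' @return List of class `exergame_sim` with elements `plan`
#'   (`movement_plan`: commanded steps, arm lifts, errors, pauses), `log`
#'   (`game_event_log`: objects with outcomes, errors, score, durations) and
#'   `avatar` (`data.frame` of body x/y at the capture rate).
#' @export
#' @examples
#' set.seed(1)
#' sched <- generate_object_schedule(game_settings("low", "without"), seed = 7)
#' sim <- simulate_play(sched, player_policy(), seed = 7)
#' sim$log$score
simulate_play <- function(schedule, policy, settings = attr(schedule, "settings"),
                          seed) {
  stopifnot(inherits(schedule, "game_schedule"), inherits(policy, "player_policy"))
  dur <- settings$trial_duration
  hw <- settings$area_half_width
  catch_hw <- settings$catch_half_width * if (isTRUE(policy$jump_catching)) 1.5 else 1

  sched <- as.data.frame(schedule)
  sched$resolve_time <- NA_real_
  falling <- which(sched$kind != "chicken")
  chicks <- which(sched$kind == "chicken")

  with_seed(seed, {
    attempt <- rep(FALSE, nrow(sched))
    if (policy$arm_style != "never") {
      attempt[chicks] <- runif(length(chicks)) < policy$arm_lift_probability
    }

    st <- new.env(parent = emptyenv())
    st$t <- 0; st$g <- 0
    st$ax <- 0; st$y <- -0.5 * hw
    st$pause_total <- 0
    st$steps <- list(); st$lifts <- list(); st$errors <- list()
    st$next_pair <- 0
    st$last_drift_t <- 0
    st$lifted_for <- integer()

    # resolve falling objects and expiring chickens in game-time (g0, g1];
    # pos_fun(gt) gives the avatar x at game time gt (NULL = constant st$ax)
    resolve_span <- function(g0, g1, pos_fun = NULL) {
      due <- falling[sched$outcome[falling] == "pending" &
                       sched$arrival[falling] > g0 & sched$arrival[falling] <= g1]
      for (i in due) {
        axi <- if (is.null(pos_fun)) st$ax else pos_fun(sched$arrival[i])
        sched$outcome[i] <<- if (sched$kind[i] == "grape") {
          if (abs(axi - sched$x[i]) <= catch_hw) "caught" else "missed"
        } else {
          if (axi >= sched$lo[i] && axi <= sched$hi[i]) "hit" else "avoided"
        }
        sched$resolve_time[i] <<- sched$arrival[i]
      }
      exp_ <- chicks[sched$outcome[chicks] == "pending" &
                       sched$arrival[chicks] > g0 & sched$arrival[chicks] <= g1]
      if (length(exp_)) {
        sched$outcome[exp_] <<- "missed"
        sched$resolve_time[exp_] <<- sched$arrival[exp_]
      }
      invisible(NULL)
    }

    advance_idle <- function(t_new) {
      # tiny positive requests are floored so floating-point slivers cannot
      # stall the event loop
      if (t_new > st$t) t_new <- max(t_new, st$t + 1e-6)
      t_new <- min(t_new, st$t + (dur - st$g))
      if (t_new <= st$t) return(invisible(NULL))
      g_new <- st$g + (t_new - st$t)
      resolve_span(st$g, g_new)
      st$t <- t_new; st$g <- g_new
    }

    exec_step <- function(foot, dx, dy, T) {
      t0 <- st$t
      ax0 <- st$ax
      g0 <- st$g
      resolve_span(g0, g0 + T, pos_fun = function(gt) {
        ax0 + (dx / 2) * mj_pos((gt - g0) / T)
      })
      st$steps[[length(st$steps) + 1L]] <-
        list(foot = foot, start = t0, end = t0 + T, dx = dx, dy = dy)
      st$ax <- ax0 + dx / 2
      st$y <- st$y + dy / 2
      st$t <- t0 + T; st$g <- st$g + T
    }

    # a lead + trailing step moving the body by (dx, dy); paused = during an
    # error break (game clock frozen, objects untouched)
    exec_pair <- function(dx, dy, paused = FALSE) {
      lead <- if (dx >= 0) "right" else "left"
      trail <- if (dx >= 0) "left" else "right"
      T1 <- policy$step_duration * runif(1, 0.9, 1.1)
      T2 <- policy$step_duration * runif(1, 0.9, 1.1)
      gap <- runif(1, 0.08, 0.15)
      if (paused) {
        for (leg in list(c(lead, T1), c(trail, T2))) {
          t0 <- st$t
          st$steps[[length(st$steps) + 1L]] <-
            list(foot = leg[1], start = t0, end = t0 + as.numeric(leg[2]),
                 dx = dx, dy = dy)
          st$ax <- st$ax + dx / 2; st$y <- st$y + dy / 2
          st$t <- t0 + as.numeric(leg[2]) + gap
        }
      } else {
        t_pair <- st$t
        exec_step(lead, dx, dy, T1)
        advance_idle(st$t + gap)
        exec_step(trail, dx, dy, T2)
        st$next_pair <- t_pair + max(st$t - t_pair + 0.15,
                                     60 / policy$cadence_preference)
      }
    }

    trigger_error <- function() {
      dir <- if (st$y > hw) "front" else if (st$y < -hw) "back"
      else if (st$ax > hw) "right" else "left"
      t_err <- st$t
      dr <- rlnorm(1, log(2), 0.35)
      tx <- max(-0.8 * hw, min(0.8 * hw, st$ax)) - st$ax
      ty <- max(-0.8 * hw, min(0.6 * hw, st$y)) - st$y
      n_pairs <- if (max(abs(tx), abs(ty)) > 0.35) 2L else 1L
      for (k in seq_len(n_pairs)) exec_pair(tx / n_pairs, ty / n_pairs, paused = TRUE)
      pause_dur <- max(dr, st$t - t_err)
      st$t <- t_err + pause_dur
      st$pause_total <- st$pause_total + pause_dur
      st$errors[[length(st$errors) + 1L]] <-
        list(start = t_err, duration = pause_dur, direction = dir)
    }

    maybe_error <- function() {
      if (abs(st$ax) > hw || abs(st$y) > hw) trigger_error()
    }

    v_eff <- policy$step_size_preference * policy$cadence_preference / 60

    # players wait for a branch to pass rather than cross its path: a target
    # is blocked while a branch in the lower part of its fall (landing within
    # ~2.5 s) overlaps the way there -- the waiting behaviour that makes
    # obstacle trials slower-paced
    path_blocked <- function(target) {
      if (settings$obstacles != "with") return(FALSE)
      b <- sched$kind == "branch" & sched$outcome == "pending" &
        sched$arrival > st$g & sched$arrival <= st$g + 4
      any(b & sched$lo <= max(st$ax, target) + 0.05 &
            sched$hi >= min(st$ax, target) - 0.05, na.rm = TRUE)
    }

    # one decision: returns TRUE if it advanced time / acted
    decide <- function() {
      g <- st$g
      # 1. branch evasion (urgent, ignores cadence pacing)
      if (settings$obstacles == "with") {
        danger <- which(sched$kind == "branch" & sched$outcome == "pending" &
                          sched$arrival > g & sched$arrival <= g + 1.5 &
                          sched$lo - 0.05 <= st$ax & st$ax <= sched$hi + 0.05)
        if (length(danger)) {
          i <- danger[which.min(sched$arrival[danger])]
          left_exit <- sched$lo[i] - 0.15
          right_exit <- sched$hi[i] + 0.15
          target <- if (abs(st$ax - left_exit) < abs(st$ax - right_exit) &&
                          left_exit > -hw) left_exit
          else if (right_exit < hw) right_exit
          else left_exit
          d <- target - st$ax
          if (abs(d) > 0.04 && st$g + 2 * policy$step_duration + 0.3 < dur) {
            exec_pair(sign(d) * min(abs(d), 0.4), drift_quantum())
            maybe_error()
            return(TRUE)
          }
        }
      }
      # 2. chickens
      act <- chicks[sched$spawn_time[chicks] <= g & sched$arrival[chicks] > g &
                      sched$outcome[chicks] == "pending" & attempt[chicks]]
      if (length(act)) {
        i <- act[1]
        ready <- sched$spawn_time[i] + policy$reaction_delay
        if (g < ready) {
          advance_idle(st$t + max(ready - g, 0.01))
          return(TRUE)
        }
        if (abs(st$ax - sched$x[i]) > 0.7 * catch_hw) {
          if (path_blocked(sched$x[i])) {
            advance_idle(st$t + 0.2)  # wait for the branch to pass
            return(TRUE)
          }
          return(move_toward(sched$x[i], urgent = TRUE))
        }
        # in position: raise the arm(s)
        ld <- runif(1, 0.8, 1.2)
        if (st$g + ld < dur) {
          side <- switch(policy$arm_style,
                         both_arms = "both",
                         one_arm = sample(c("left", "right"), 1L))
          st$lifts[[length(st$lifts) + 1L]] <-
            list(side = side, start = st$t, end = st$t + ld)
          sched$outcome[i] <<- "caught"
          sched$resolve_time[i] <<- g
          t_end <- st$t + ld
          resolve_span(st$g, st$g + ld)
          st$t <- t_end; st$g <- st$g + ld
          return(TRUE)
        }
      }
      # 3. grapes
      cand <- falling[sched$kind[falling] == "grape" &
                        sched$outcome[falling] == "pending" &
                        sched$arrival[falling] > g + 0.15]
      if (length(cand)) {
        tta <- sched$arrival[cand] - g - policy$reaction_delay
        reach <- abs(sched$x[cand] - st$ax) <= pmax(0, tta) * v_eff + catch_hw
        cand <- cand[reach]
        if (length(cand)) {
          open <- !vapply(sched$x[cand], path_blocked, TRUE)
          cand <- cand[open]
        }
        if (length(cand)) {
          i <- cand[which.min(sched$arrival[cand])]
          if (abs(sched$x[i] - st$ax) > 0.08) {
            # an imminent arrival overrides the comfortable stepping pace
            return(move_toward(sched$x[i],
                               urgent = sched$arrival[i] - g < 1.8))
          }
          # parked under it: wait (capped so chickens can still interrupt)
          advance_idle(st$t + min(0.5, max(0.05, sched$arrival[i] - g)))
          return(TRUE)
        }
      }
      FALSE
    }

    drift_quantum <- function() {
      q <- policy$forward_drift_rate / 60 * (st$t - st$last_drift_t)
      st$last_drift_t <- st$t
      min(q, 0.06) + rnorm(1, 0, 0.3 * policy$lateral_noise)
    }

    move_toward <- function(target, urgent = FALSE) {
      if (!urgent && st$t < st$next_pair) {
        advance_idle(st$next_pair)
        return(TRUE)
      }
      d <- target - st$ax
      size <- min(policy$step_size_preference * exp(rnorm(1, 0, 0.12)), abs(d))
      if (size < 0.06) size <- 0.06
      dx <- sign(d) * size + rnorm(1, 0, policy$lateral_noise)
      if (st$g + 2 * policy$step_duration + 0.3 >= dur) {
        advance_idle(st$t + (dur - st$g))
        return(TRUE)
      }
      exec_pair(dx, drift_quantum())
      maybe_error()
      TRUE
    }

    it <- 0L
    while (st$g < dur - 1e-9) {
      it <- it + 1L
      if (it > 500000L) {
        stop_exerstep("RunawaySimulation", sprintf(
          "simulation failed to progress (t=%.4f g=%.4f ax=%.4f y=%.4f steps=%d next_pair=%.4f)",
          st$t, st$g, st$ax, st$y, length(st$steps), st$next_pair))
      }
      acted <- decide()
      if (!acted) {
        nxt <- suppressWarnings(min(
          sched$arrival[sched$outcome == "pending" & sched$arrival > st$g],
          sched$spawn_time[chicks][sched$spawn_time[chicks] > st$g]
        ))
        if (!is.finite(nxt)) nxt <- dur
        advance_idle(st$t + max(0.05, min(nxt, dur) - st$g))
      }
    }

    # the last action may overrun the nominal game end by a fraction of a
    # second; the recording simply keeps what actually happened
    active_time <- st$g
    wall_dur <- st$t
    plan <- structure(
      list(
        duration = wall_dur, game_duration = dur, rate = settings$rate,
        init = list(x = 0, y = -0.5 * hw, stance = 0.25),
        steps = bind_rows_list(st$steps,
                               c("foot", "start", "end", "dx", "dy")),
        lifts = bind_rows_list(st$lifts, c("side", "start", "end")),
        errors = bind_rows_list(st$errors, c("start", "duration", "direction")),
        policy = policy
      ),
      class = "movement_plan"
    )
    log <- game_event_log(sched, plan$errors, settings,
                          active = active_time, pauses = st$pause_total)
    avatar <- body_path(plan)
    structure(list(plan = plan, log = log, avatar = avatar),
              class = "exergame_sim")
  })
}

bind_rows_list <- function(lst, cols) {
  if (!length(lst)) {
    out <- lapply(cols, function(cn) {
      if (cn %in% c("foot", "side", "direction")) character() else numeric()
    })
    names(out) <- cols
    return(as.data.frame(out))
  }
  out <- do.call(rbind, lapply(lst, function(r) as.data.frame(r)))
  rownames(out) <- NULL
  out[, cols]
}

# Body (= avatar/trunk) horizontal path implied by a movement plan, sampled
# at the capture rate. Each step moves the body by half the step's
# displacement along a minimum-jerk profile.
body_path <- function(plan, times = NULL) {
  if (is.null(times)) {
    times <- seq(0, plan$duration, by = 1 / plan$rate)
  }
  x <- rep(plan$init$x, length(times))
  y <- rep(plan$init$y, length(times))
  s <- plan$steps
  if (nrow(s)) for (i in seq_len(nrow(s))) {
    tau <- (times - s$start[i]) / (s$end[i] - s$start[i])
    prof <- mj_pos(tau)
    x <- x + (s$dx[i] / 2) * prof
    y <- y + (s$dy[i] / 2) * prof
  }
  data.frame(t = times, x = x, y = y)
}

#' @export
print.exergame_sim <- function(x, ...) {
  cat(sprintf(
    "<exergame_sim> %s speed, %s obstacles: score %d, %d steps, %d lifts, %d error msg\n",
    x$log$meta$speed, x$log$meta$obstacles, x$log$score,
    nrow(x$plan$steps), nrow(x$plan$lifts), nrow(x$log$errors)
  ))
  invisible(x)
}
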