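#' Generate the object schedule for one trial
#'
#' Spawns grapes, branches (obstacle condition only) and chickens for a trial
#' in game time. Falling objects keep their concurrency inside the configured
#' range at every instant: the schedule starts with the range minimum on
#' screen, immediately respawns whenever a landing would drop the count below
#' the minimum, and occasionally spawns an extra object while below the
#' maximum. Fall times are drawn uniformly from the speed's range. Chickens
#' get non-overlapping windows placed uniformly over the trial.
#'
#' @param settings a [game_settings()].
#' @param seed integer seed; the schedule is reproducible given the seed.
#' @return `data.frame` of class `game_schedule` with one row per object:
#'   `kind` (`grape`/`branch`/`chicken`), `spawn_time`, `fall_time` (`NA` for
#'   chickens), `arrival` (landing time; for chickens the window end), `x`
#'   (lateral centre, m), `lo`/`hi` (branch extent, `NA` otherwise) and
#'   `outcome` (`"pending"`). Carries `settings` as an attribute.
#' @export
#' @examples
#' sched <- generate_object_schedule(game_settings("low", "with"), seed = 1)
#' table(sched$kind)
generate_object_schedule <- function(settings, seed) {
  stopifnot(inherits(settings, "game_settings"))
  dur <- settings$trial_duration
  slack <- dur - settings$chickens_per_trial * settings$chicken_window
  if (dur <= 0 || slack < 0) {
    stop_exerstep("ScheduleInfeasible", sprintf(
      "cannot place %d non-overlapping %g s chicken windows in a %g s trial",
      settings$chickens_per_trial, settings$chicken_window, dur
    ))
  }
  hw <- settings$area_half_width
  with_seed(seed, {
    # chickens: disjoint windows via a uniform partition of the slack time
    nc <- settings$chickens_per_trial
    g <- runif(nc + 1L)
    gaps <- g / sum(g) * slack
    starts <- cumsum(gaps)[seq_len(nc)] + (seq_len(nc) - 1L) * settings$chicken_window
    chick <- data.frame(
      kind = rep("chicken", nc), spawn_time = starts, fall_time = NA_real_,
      arrival = starts + settings$chicken_window,
      x = runif(nc, -0.9 * hw, 0.9 * hw), lo = NA_real_, hi = NA_real_
    )

    stream <- function(kind, conc, half_extent) {
      spawn <- function(t) {
        ft <- runif(1, settings$fall_time_range[1], settings$fall_time_range[2])
        x <- runif(1, -(hw - half_extent), hw - half_extent)
        data.frame(kind = kind, spawn_time = t, fall_time = ft, arrival = t + ft,
                   x = x, lo = x - half_extent, hi = x + half_extent)
      }
      objs <- lapply(seq_len(conc[1]), function(i) spawn(0))
      active <- vapply(objs, function(o) o$arrival, 0)
      repeat {
        ta <- min(active)
        if (ta > dur) break
        active <- active[-which.min(active)]
        extra <- length(active) < conc[2] && runif(1) < 0.35
        need <- max(0L, conc[1] - length(active)) + as.integer(extra)
        need <- min(need, conc[2] - length(active))
        for (i in seq_len(need)) {
          o <- spawn(ta)
          objs[[length(objs) + 1L]] <- o
          active <- c(active, o$arrival)
        }
      }
      do.call(rbind, objs)
    }

    out <- rbind(chick, stream("grape", settings$grape_concurrency, 0))
    if (settings$obstacles == "with") {
      out <- rbind(out, stream("branch", settings$branch_concurrency,
                               settings$branch_width / 2))
    }
    out <- out[order(out$spawn_time), ]
    rownames(out) <- NULL
    out$outcome <- "pending"
    structure(out, settings = settings, seed = seed,
              class = c("game_schedule", "data.frame"))
  })
}

# concurrency of falling objects of one kind over time; used by tests and
# validation. Returns the count on the half-open spans between events.
schedule_concurrency <- function(sched, kind) {
  s <- sched[sched$kind == kind, , drop = FALSE]
  if (!nrow(s)) return(data.frame(from = numeric(), to = numeric(), count = integer()))
  dur <- attr(sched, "settings")$trial_duration
  pts <- sort(unique(c(0, s$spawn_time, pmin(s$arrival, dur), dur)))
  from <- head(pts, -1L); to <- tail(pts, -1L)
  mid <- (from + to) / 2
  count <- vapply(mid, function(t) sum(s$spawn_time <= t & s$arrival > t), 0L)
  data.frame(from = from, to = to, count = count)
}
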