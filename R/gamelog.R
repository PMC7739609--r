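# Structured game event logs. The original study recovered scores and error
# messages by running OCR over screen captures; here the log is a first-class
# structured record (and the simulator emits it directly). OCR is explicitly
# out of scope.

game_event_log <- function(objects, errors, settings, active, pauses,
                           meta = list()) {
  meta <- modifyList(list(speed = settings$speed, obstacles = settings$obstacles),
                     meta)
  log <- structure(
    list(objects = as.data.frame(objects), errors = errors,
         weights = settings$score_weights, meta = meta,
         durations = list(active = active, pauses = pauses,
                          recording = active + pauses)),
    class = "game_event_log"
  )
  log$score <- score_trial(log)$score
  log
}

#' @export
print.game_event_log <- function(x, ...) {
  s <- score_trial(x)
  cat(sprintf("<game_event_log> %s speed, %s obstacles: score %d\n",
              x$meta$speed, x$meta$obstacles, s$score))
  cat(sprintf("  grapes %d/%d, chickens %d/%d, branches hit %d/%d, %d error msg\n",
              s$grapes["caught"], s$grapes["presented"],
              s$chickens["caught"], s$chickens["presented"],
              s$branches["hit"], s$branches["presented"], nrow(x$errors)))
  invisible(x)
}

#' Score a trial from its game event log
#'
#' Recounts outcome records and applies the score weights: +1 per grape
#' caught, +3 per chicken caught, -2 per branch hit. Objects still pending at
#' trial end (spawned but not yet resolved) are not counted as presented.
#'
#' @param log a `game_event_log`.
#' @param weights named numeric score weights (`grape`, `chicken`,
#'   `branch`); defaults to the log's own.
#' @return List of class `game_score_summary`: `score`, and per object kind
#'   the presented/caught (or hit) counts and percentage (`NA` when nothing
#'   was presented).
#' @export
#' @examples
#' sched <- generate_object_schedule(game_settings("low", "with"), seed = 2)
#' sim <- simulate_play(sched, player_policy(), seed = 2)
#' score_trial(sim$log)
score_trial <- function(log, weights = NULL) {
  if (!inherits(log, "game_event_log")) {
    stop_exerstep("LogParseError", "`log` must be a game_event_log")
  }
  if (is.null(weights)) weights <- log$weights
  o <- log$objects
  need <- c("kind", "outcome")
  if (!all(need %in% names(o))) {
    stop_exerstep("LogParseError", "log objects lack kind/outcome fields")
  }
  bad <- !o$outcome %in% c("caught", "missed", "hit", "avoided", "pending")
  if (any(bad)) {
    stop_exerstep("LogParseError",
                  sprintf("malformed outcome record(s): %s",
                          paste(unique(o$outcome[bad]), collapse = ", ")))
  }
  cnt <- function(kind, good) {
    k <- o$kind == kind & o$outcome != "pending"
    pres <- sum(k)
    got <- sum(k & o$outcome == good)
    c(presented = pres, n = got, pct = if (pres) 100 * got / pres else NA_real_)
  }
  g <- cnt("grape", "caught")
  c_ <- cnt("chicken", "caught")
  b <- cnt("branch", "hit")
  structure(list(
    score = as.integer(weights[["grape"]] * g[["n"]] +
                         weights[["chicken"]] * c_[["n"]] +
                         weights[["branch"]] * b[["n"]]),
    grapes = c(presented = g[["presented"]], caught = g[["n"]], pct = g[["pct"]]),
    chickens = c(presented = c_[["presented"]], caught = c_[["n"]], pct = c_[["pct"]]),
    branches = c(presented = b[["presented"]], hit = b[["n"]], pct = b[["pct"]])
  ), class = "game_score_summary")
}

#' @export
print.game_score_summary <- function(x, ...) {
  cat(sprintf("score %d | grapes %d/%d (%.1f%%) | chickens %d/%d (%.1f%%) | branches hit %d/%d\n",
              x$score, x$grapes["caught"], x$grapes["presented"], x$grapes["pct"],
              x$chickens["caught"], x$chickens["presented"], x$chickens["pct"],
              x$branches["hit"], x$branches["presented"]))
  invisible(x)
}

#' Write / read a game event log as JSON lines
#'
#' One JSON object per line: a `meta` record, one record per game object,
#' one per error message, and a closing `summary` record.
#'
#' @param log a `game_event_log`.
#' @param path file path (conventionally `.jsonl`).
#' @return `path` / the reconstructed `game_event_log`.
#' @export
write_game_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(x) writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, na = "null",
                                                  digits = 10), con)
  emit(c(list(record = "meta"), log$meta,
         list(weights = as.list(log$weights), durations = log$durations)))
  o <- log$objects
  for (i in seq_len(nrow(o))) {
    emit(list(record = "object", kind = o$kind[i], spawn_time = o$spawn_time[i],
              fall_time = o$fall_time[i], arrival = o$arrival[i], x = o$x[i],
              lo = o$lo[i], hi = o$hi[i], outcome = o$outcome[i],
              resolve_time = o$resolve_time[i]))
  }
  e <- log$errors
  for (i in seq_len(nrow(e))) {
    emit(list(record = "error", start = e$start[i], duration = e$duration[i],
              direction = e$direction[i]))
  }
  emit(list(record = "summary", score = log$score))
  invisible(path)
}

#' @rdname write_game_log
#' @export
read_game_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_exerstep("LogParseError", sprintf("empty log: %s", path))
  recs <- lapply(lines, function(l) {
    tryCatch(jsonlite::fromJSON(l),
             error = function(e) stop_exerstep("LogParseError",
                                               sprintf("bad JSON line in %s", path)))
  })
  kinds <- vapply(recs, function(r) r$record %||% "", "")
  meta_rec <- recs[[which(kinds == "meta")[1]]]
  null2na <- function(x) if (is.null(x)) NA else x
  obj <- do.call(rbind, lapply(recs[kinds == "object"], function(r) {
    data.frame(kind = r$kind, spawn_time = null2na(r$spawn_time),
               fall_time = as.numeric(null2na(r$fall_time)),
               arrival = null2na(r$arrival), x = null2na(r$x),
               lo = as.numeric(null2na(r$lo)), hi = as.numeric(null2na(r$hi)),
               outcome = r$outcome,
               resolve_time = as.numeric(null2na(r$resolve_time)))
  }))
  if (is.null(obj)) obj <- data.frame(kind = character(), outcome = character())
  errs <- do.call(rbind, lapply(recs[kinds == "error"], function(r) {
    data.frame(start = r$start, duration = r$duration, direction = r$direction)
  }))
  if (is.null(errs)) {
    errs <- data.frame(start = numeric(), duration = numeric(),
                       direction = character())
  }
  settings_like <- list(speed = meta_rec$speed, obstacles = meta_rec$obstacles,
                        score_weights = unlist(meta_rec$weights))
  meta <- meta_rec[setdiff(names(meta_rec), c("record", "weights", "durations"))]
  game_event_log(obj, errs, settings = settings_like,
                 active = meta_rec$durations$active,
                 pauses = meta_rec$durations$pauses, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tally error messages across trials
#'
#' Builds the 2 x 2 speed-by-obstacles table of error-message counts, the
#' per-direction breakdown with mean resolution times, and the number of
#' valid trials (trials contributing a log).
#'
#' @param logs list of `game_event_log` objects, each tagged with `speed` and
#'   `obstacles` in its `meta`.
#' @return List of class `error_tally`: `cells` (2 x 2 matrix, rows
#'   low/high speed, columns without/with obstacles), `total`,
#'   `by_direction` (`data.frame` of counts and mean resolution seconds),
#'   `valid_trials`.
#' @export
tally_errors <- function(logs) {
  cells <- matrix(0L, 2, 2, dimnames = list(speed = c("low", "high"),
                                            obstacles = c("without", "with")))
  dirs <- c("front", "back", "left", "right")
  cnt <- setNames(integer(length(dirs)), dirs)
  dur <- setNames(vector("list", length(dirs)), dirs)
  for (log in logs) {
    e <- log$errors
    cells[log$meta$speed, log$meta$obstacles] <-
      cells[log$meta$speed, log$meta$obstacles] + nrow(e)
    for (i in seq_len(nrow(e))) {
      d <- e$direction[i]
      cnt[d] <- cnt[d] + 1L
      dur[[d]] <- c(dur[[d]], e$duration[i])
    }
  }
  structure(list(
    cells = cells,
    total = sum(cells),
    by_direction = data.frame(
      direction = dirs, n = as.integer(cnt),
      mean_resolution = vapply(dur, function(x) if (length(x)) mean(x) else NA_real_, 0)
    ),
    valid_trials = length(logs)
  ), class = "error_tally")
}

#' Mean error messages per trial
#'
#' @param tally an `error_tally` (or anything with `total` and
#'   `valid_trials`).
#' @return Messages per valid trial.
#' @export
#' @examples
#' mean_errors_per_trial(list(total = 43, valid_trials = 113))  # 0.3805
mean_errors_per_trial <- function(tally) {
  if (is.null(tally$valid_trials) || tally$valid_trials <= 0) {
    stop_exerstep("UndefinedRate", "no valid trials: rate undefined")
  }
  tally$total / tally$valid_trials
}

#' Pearson chi-squared test for a 2 x 2 table
#'
#' Plain Pearson statistic without continuity correction, 1 degree of
#' freedom. The no-correction choice reproduces the study's printed value on
#' its error-message table (a Yates-corrected statistic would not).
#'
#' @param table 2 x 2 matrix of non-negative counts.
#' @return List `statistic`, `df` (1), `p`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(5, 17, 8, 13), 2))  # statistic 1.203
chi_square_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L)) || any(m < 0) || any(!is.finite(m))) {
    stop_exerstep("DegenerateTable", "need a 2 x 2 matrix of non-negative counts")
  }
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(rs == 0) || any(cs == 0)) {
    stop_exerstep("DegenerateTable", "zero row or column margin")
  }
  expected <- outer(rs, cs) / n
  stat <- sum((m - expected)^2 / expected)
  list(statistic = stat, df = 1L, p = pchisq(stat, 1L, lower.tail = FALSE))
}
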