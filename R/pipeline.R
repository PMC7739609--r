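#' Run configuration
#'
#' @param seed master seed; all randomness in a run flows from it.
#' @param n_participants cohort size.
#' @param out_dir output directory (created if needed).
#' @param settings_overrides named list forwarded to [game_settings()].
#' @param detection a [detection_config()].
#' @param responses metrics to model.
#' @param noise_sd marker noise for synthesis, m.
#' @param render_heatmap also write a PNG of the pooled heatmap.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, n_participants = 15, out_dir = "exerstep_run",
                       settings_overrides = list(),
                       detection = detection_config(),
                       responses = c("single_support_duration",
                                     "single_support_ratio", "step_size",
                                     "cadence", "arm_lift_frequency"),
                       noise_sd = 0.002, render_heatmap = TRUE) {
  if (!is_scalar_number(seed)) stop_exerstep("ConfigError", "seed must be a number")
  check_scalar_number(n_participants, "n_participants", 0)
  if (!inherits(detection, "detection_config")) {
    stop_exerstep("ConfigError", "`detection` must be a detection_config()")
  }
  structure(list(seed = as.integer(seed), n_participants = n_participants,
                 out_dir = out_dir, settings_overrides = settings_overrides,
                 detection = detection, responses = responses,
                 noise_sd = noise_sd, render_heatmap = render_heatmap),
            class = "run_config")
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

steps_long <- function(trial_id, steps, lifts) {
  ev <- list()
  for (f in c("left", "right")) {
    s <- steps[[f]]
    if (nrow(s)) {
      ev[[f]] <- data.frame(trial = trial_id, event = "step", side = f,
                            start = s$start, end = s$end, size = s$size)
    }
  }
  if (nrow(lifts)) {
    ev$lift <- data.frame(trial = trial_id, event = "arm_lift", side = lifts$side,
                          start = lifts$start, end = lifts$end, size = NA_real_)
  }
  if (!length(ev)) {
    return(data.frame(trial = character(), event = character(), side = character(),
                      start = numeric(), end = numeric(), size = numeric()))
  }
  do.call(rbind, ev)
}

summarize_game_tables <- function(logs) {
  rows <- lapply(logs, function(log) {
    s <- score_trial(log)
    data.frame(speed = log$meta$speed, obstacles = log$meta$obstacles,
               score = s$score, grapes_pct = s$grapes[["pct"]],
               chickens_pct = s$chickens[["pct"]],
               branches_pct = s$branches[["pct"]])
  })
  d <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(score, grapes_pct, chickens_pct, branches_pct) ~
                            speed + obstacles, data = d, FUN = mean, na.action = NULL,
                          na.rm = TRUE)
  agg[order(agg$obstacles, agg$speed), ]
}

#' Run the full synthetic study
#'
#' Simulates a cohort, renders and re-loads nothing (the in-memory chain is
#' used), detects events, computes metrics, scores logs, fits the configured
#' mixed models, and writes all artifacts to `cfg$out_dir`: a cohort
#' manifest, per-trial event and metrics tables, score and error-message
#' summaries, the pooled heatmap (matrix and optional PNG), a model report,
#' and a machine-readable `report.json` describing every artifact plus
#' internal consistency checks (score identity, clock accounting,
#' ground-truth step-count agreement).
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list with the run `report`, the metrics `table` and
#'   the `fits`.
#' @export
run_synthetic_study <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  add_art <- function(p) artifacts[length(artifacts) + 1L] <<- p

  coh <- make_cohort(cfg$n_participants, seed = cfg$seed,
                     settings_overrides = cfg$settings_overrides,
                     render = TRUE, noise_sd = cfg$noise_sd)
  if (!length(coh)) stop_exerstep("RunFailed", "empty cohort")

  manifest <- do.call(rbind, lapply(seq_along(coh), function(i) {
    m <- coh[[i]]$meta
    data.frame(trial = i, participant = m$participant, gender = m$gender,
               speed = m$speed, obstacles = m$obstacles, repetition = m$repetition,
               duration = coh[[i]]$recording$duration,
               score = coh[[i]]$sim$log$score)
  }))
  add_art(write_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv")))

  checks <- list()
  metrics <- list(); events <- list(); logs <- list()
  heat <- NULL
  gt_step_match <- 0L
  for (i in seq_along(coh)) {
    e <- coh[[i]]
    tm <- compute_trial_metrics(e$recording, cfg$detection)
    metrics[[i]] <- tm
    events[[i]] <- steps_long(sprintf("T%03d", i), tm$steps, tm$lifts)
    logs[[i]] <- e$sim$log
    heat <- if (is.null(heat)) tm$heatmap$counts else heat + tm$heatmap$counts
    gt_n <- nrow(e$truth$steps$left) + nrow(e$truth$steps$right)
    det_n <- nrow(tm$steps$left) + nrow(tm$steps$right)
    if (gt_n == det_n) gt_step_match <- gt_step_match + 1L
  }
  add_art(write_tsv(do.call(rbind, events), file.path(cfg$out_dir, "events.tsv")))

  tab <- assemble_metrics_table(metrics)
  add_art(write_tsv(tab, file.path(cfg$out_dir, "metrics.tsv")))

  add_art(write_tsv(summarize_game_tables(logs),
                    file.path(cfg$out_dir, "game_summary.tsv")))
  tally <- tally_errors(logs)
  add_art(write_tsv(as.data.frame.table(tally$cells, responseName = "n"),
                    file.path(cfg$out_dir, "error_tally.tsv")))

  add_art(write_tsv(as.data.frame(heat), file.path(cfg$out_dir, "heatmap.tsv")))
  if (isTRUE(cfg$render_heatmap)) {
    png_path <- file.path(cfg$out_dir, "heatmap.png")
    grDevices::png(png_path, width = 600, height = 600)
    graphics::image(seq(-1.5, 1.5, length.out = nrow(heat)),
                    seq(-1.5, 1.5, length.out = ncol(heat)),
                    heat, xlab = "X (m)", ylab = "Y (m)",
                    main = "Sternum occupancy", col = grDevices::hcl.colors(24))
    graphics::rect(-1, -1, 1, 1, border = "white", lwd = 2)
    grDevices::dev.off()
    add_art(png_path)
  }

  fits <- list()
  if (cfg$n_participants >= 2) {
    frows <- list()
    for (resp in cfg$responses) {
      fit <- fit_lmm(tab, lmm_spec(resp))
      fits[[resp]] <- fit
      et <- effect_tests(fit)
      co <- fit$coefficients
      co <- co[!is.na(co$effect), ]
      frows[[resp]] <- data.frame(response = resp, effect = co$effect,
                                  estimate = co$estimate, df = co$df,
                                  ci_lo = co$ci_lo, ci_hi = co$ci_hi, p = co$p)
    }
    add_art(write_tsv(do.call(rbind, frows),
                      file.path(cfg$out_dir, "model_report.tsv")))
  } else {
    checks$model_stage <- "skipped: fewer than 2 participants"
  }

  checks$score_identity <- all(vapply(logs, function(l) {
    s <- score_trial(l)
    l$score == s$score
  }, TRUE))
  checks$clock_accounting <- all(vapply(logs, function(l) {
    abs(l$durations$active + l$durations$pauses - l$durations$recording) < 1e-6
  }, TRUE))
  checks$gt_step_count_agreement <- gt_step_match / length(coh)
  checks$errors_per_trial <- mean_errors_per_trial(tally)

  report <- list(
    seed = cfg$seed, n_participants = cfg$n_participants,
    n_trials = length(coh),
    detection = unclass(cfg$detection),
    artifacts = artifacts, checks = checks
  )
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(report = report, table = tab, fits = fits))
}

#' Analyze existing recordings and logs
#'
#' The same artifact set as [run_synthetic_study()] but starting from files:
#' trajectory recordings (plus optional JSON-lines game logs with matching
#' base names). Files that fail to load or validate are reported and
#' skipped; the run fails only if no trial succeeds.
#'
#' @param paths character vector of recording files.
#' @param cfg a [run_config()] (`n_participants` ignored).
#' @param log_paths optional character vector of game-log files, parallel to
#'   `paths` (NA entries allowed).
#' @return Invisibly, list with `report`, `table`, `failures`.
#' @export
run_on_recordings <- function(paths, cfg = run_config(), log_paths = NULL) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!length(paths)) stop_exerstep("RunFailed", "no input recordings")
  metrics <- list(); failures <- list(); logs <- list()
  for (i in seq_along(paths)) {
    res <- tryCatch({
      rec <- load_recording(paths[i])
      rec <- fill_gaps(rec)
      if (is.null(rec$meta$participant)) {
        rec$meta$participant <- tools::file_path_sans_ext(basename(paths[i]))
      }
      compute_trial_metrics(rec, cfg$detection)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[paths[i]]] <- conditionMessage(res)
    } else {
      metrics[[length(metrics) + 1L]] <- res
      if (!is.null(log_paths) && !is.na(log_paths[i])) {
        logs[[length(logs) + 1L]] <- read_game_log(log_paths[i])
      }
    }
  }
  if (!length(metrics)) {
    stop_exerstep("RunFailed", sprintf("all %d input(s) failed: %s",
                                       length(paths),
                                       paste(unlist(failures), collapse = "; ")))
  }
  rows <- do.call(rbind, lapply(seq_along(metrics), function(i) {
    m <- metrics[[i]]
    data.frame(trial = i,
               participant = m$meta$participant %||% sprintf("T%03d", i),
               m$per_foot)
  }))
  add <- write_tsv(rows, file.path(cfg$out_dir, "metrics_per_foot.tsv"))
  artifacts <- add
  if (length(logs)) {
    tally <- tally_errors(logs)
    artifacts <- c(artifacts,
                   write_tsv(as.data.frame.table(tally$cells, responseName = "n"),
                             file.path(cfg$out_dir, "error_tally.tsv")))
  }
  report <- list(n_inputs = length(paths), n_ok = length(metrics),
                 failures = failures, artifacts = artifacts)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(report = report, table = rows, failures = failures))
}
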