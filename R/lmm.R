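#' Assemble the long-format study metrics table
#'
#' One row per trial x side x metric. Side-specific metrics (single-support
#' duration and ratio, step size, cadence, arm-lift frequency) contribute a
#' row per body side; trial-level metrics (anterior drift) one row with
#' `side = "none"`. Missing values (e.g. mean step size of a foot that never
#' stepped) are preserved as `NA` and dropped per-model at fit time.
#'
#' @param metrics list of `trial_metrics` (from [compute_trial_metrics()]),
#'   each carrying `participant`, `gender`, `speed`, `obstacles`,
#'   `repetition` in its `meta`.
#' @return `data.frame` of class `metrics_table` with columns `participant`,
#'   `gender`, `speed`, `obstacles`, `repetition`, `side`, `metric`, `value`.
#' @export
assemble_metrics_table <- function(metrics) {
  rows <- lapply(metrics, function(m) {
    meta <- m$meta
    need <- c("participant", "gender", "speed", "obstacles", "repetition")
    miss <- setdiff(need, names(meta))
    if (length(miss)) {
      stop_exerstep("ConfigError",
                    sprintf("trial metadata lacks: %s", paste(miss, collapse = ", ")))
    }
    base <- data.frame(participant = meta$participant, gender = meta$gender,
                       speed = meta$speed, obstacles = meta$obstacles,
                       repetition = meta$repetition)
    pf <- m$per_foot
    side_rows <- do.call(rbind, lapply(c("left", "right"), function(f) {
      r <- pf[pf$foot == f, ]
      arm <- unname(m$arm_lifts[f])
      data.frame(base, side = f,
                 metric = c("single_support_duration", "single_support_ratio",
                            "step_size", "cadence", "arm_lift_frequency"),
                 value = c(r$mean_duration, r$ratio, r$mean_step_size,
                           r$cadence, arm))
    }))
    trial_rows <- data.frame(base, side = "none", metric = "anterior_drift",
                             value = m$anterior_drift)
    rbind(side_rows, trial_rows)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(participant = character(), gender = character(),
                      speed = character(), obstacles = character(),
                      repetition = integer(), side = character(),
                      metric = character(), value = numeric())
  }
  key <- with(out, paste(participant, speed, obstacles, repetition, side, metric))
  if (anyDuplicated(key)) {
    stop_exerstep("DuplicateRow",
                  sprintf("duplicate metric rows, e.g. %s", key[duplicated(key)][1]))
  }
  rownames(out) <- NULL
  class(out) <- c("metrics_table", "data.frame")
  out
}

#' Mixed-model specification
#'
#' The study design model: fixed effects of game speed, obstacles, trial
#' repetition, gender and body side; random intercepts per participant plus
#' a by-participant random slope for side; REML estimation. Factors use
#' treatment coding with reference levels low speed, without obstacles,
#' repetition 1, female, left side.
#'
#' @param response metric name to model.
#' @param fixed character vector of fixed effects.
#' @param random `"side_slope"` (intercept + by-participant side slope) or
#'   `"intercept"`.
#' @param reml fit by REML (default `TRUE`).
#' @return List of class `lmm_spec`.
#' @export
lmm_spec <- function(response,
                     fixed = c("speed", "obstacles", "repetition", "gender", "side"),
                     random = c("side_slope", "intercept"),
                     reml = TRUE) {
  random <- match.arg(random)
  structure(list(response = response, fixed = fixed, random = random,
                 reml = reml), class = "lmm_spec")
}

code_factors <- function(d) {
  lv <- list(speed = c("low", "high"), obstacles = c("without", "with"),
             gender = c("female", "male"), side = c("left", "right"))
  for (nm in names(lv)) {
    if (nm %in% names(d)) d[[nm]] <- factor(d[[nm]], levels = lv[[nm]])
  }
  if ("repetition" %in% names(d)) d$repetition <- factor(d$repetition)
  d
}

#' Fit the study's linear mixed-effects model
#'
#' REML fit via \pkg{lme4}. Per-coefficient tests use a between-within
#' (containment) denominator-degrees-of-freedom approximation: effects that
#' vary within participants get `N - n_participants - p_within` df, purely
#' between-participant effects (gender) get `n_participants - q_between` df.
#' The df method is recorded in the fit; calibration (null p-value
#' uniformity, CI coverage) is validated by simulation rather than by
#' matching any particular reference df.
#'
#' @param table a [assemble_metrics_table()] result (or compatible
#'   `data.frame`).
#' @param spec an [lmm_spec()].
#' @return List of class `lmm_fit`: `coefficients` (`data.frame` with
#'   estimate, se, df, t, p, 95% CI), `varcomp`, `model` (the `lmerMod`),
#'   `n_obs`, `n_dropped`, `singular`, `converged`, `df_method`.
#' @export
fit_lmm <- function(table, spec) {
  stopifnot(inherits(spec, "lmm_spec"))
  d <- as.data.frame(table)
  d <- d[d$metric == spec$response, , drop = FALSE]
  if (!nrow(d)) {
    stop_exerstep("ConfigError",
                  sprintf("no rows for response '%s'", spec$response))
  }
  fixed <- spec$fixed
  if (all(d$side == "none")) fixed <- setdiff(fixed, "side")
  n_drop <- sum(is.na(d$value))
  d <- d[!is.na(d$value), , drop = FALSE]
  d <- code_factors(d)
  if (length(unique(d$participant)) < 2) {
    stop_exerstep("ConfigError", "need >= 2 participants to fit the mixed model")
  }
  # drop constant factors (e.g. single-gender subsets) rather than fail
  fixed <- fixed[vapply(fixed, function(f) length(unique(d[[f]])) > 1, TRUE)]
  ran <- if (spec$random == "side_slope" && "side" %in% fixed) {
    "(1 + side | participant)"
  } else {
    "(1 | participant)"
  }
  form <- stats::as.formula(paste("value ~", paste(c(fixed, ran), collapse = " + ")))
  fit <- suppressMessages(lme4::lmer(form, data = d, REML = spec$reml))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  # optimizer exit status; the gradient-check messages lme4 emits on top of
  # this are recorded but not treated as failures
  conv <- isTRUE(fit@optinfo$conv$opt == 0)
  conv_msgs <- unlist(fit@optinfo$conv$lme4$messages)

  sm <- summary(fit)$coefficients
  X <- lme4::getME(fit, "X")
  p_rank <- qr(X)$rank
  n_subj <- length(unique(d$participant))
  N <- nrow(d)
  # classify each coefficient as between- or within-participant
  coef_names <- rownames(sm)
  term_of <- setNames(rep(NA_character_, length(coef_names)), coef_names)
  for (f in fixed) {
    hits <- startsWith(coef_names, f)
    term_of[hits] <- f
  }
  between <- vapply(fixed, function(f) {
    all(tapply(as.character(d[[f]]), d$participant,
               function(x) length(unique(x))) == 1L)
  }, TRUE)
  q_b <- 1L + sum(vapply(coef_names[!is.na(term_of)],
                         function(cn) isTRUE(between[term_of[cn]]), TRUE))
  df_between <- max(1L, n_subj - q_b)
  df_within <- max(1L, N - n_subj - (p_rank - q_b))
  dfs <- vapply(coef_names, function(cn) {
    f <- term_of[cn]
    if (!is.na(f) && isTRUE(between[f])) df_between else df_within
  }, 0)
  dfs["(Intercept)"] <- df_between

  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  tval <- est / se
  pval <- 2 * pt(-abs(tval), dfs)
  crit <- qt(0.975, dfs)
  coefs <- data.frame(
    term = coef_names, effect = unname(term_of), estimate = unname(est),
    se = unname(se), df = unname(dfs), t = unname(tval),
    ci_lo = unname(est - crit * se), ci_hi = unname(est + crit * se),
    p = unname(pval)
  )
  rownames(coefs) <- NULL

  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    response = spec$response, coefficients = coefs, varcomp = vc,
    model = fit, n_obs = N, n_dropped = n_drop, n_participants = n_subj,
    singular = singular, converged = conv, messages = conv_msgs,
    df_method = "between-within (containment)",
    spec = spec
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s: %d obs (%d dropped), %d participants; df: %s%s\n",
              x$response, x$n_obs, x$n_dropped, x$n_participants, x$df_method,
              if (x$singular) " [singular fit]" else ""))
  print(format(x$coefficients, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Per-effect conditional F-tests
#'
#' One test per fixed effect. All study factors are two-level, so each
#' effect has one coefficient and the F statistic is the squared t from the
#' fit, with 1 numerator df and the between-within denominator df.
#'
#' @param fit an [fit_lmm()] result.
#' @return `data.frame`: `effect`, `statistic` (F), `df1`, `df2`, `p`.
#' @export
effect_tests <- function(fit) {
  if (!inherits(fit, "lmm_fit") || !isTRUE(fit$converged)) {
    stop_exerstep("TestUnavailable", "need a converged lmm_fit")
  }
  co <- fit$coefficients
  co <- co[!is.na(co$effect), , drop = FALSE]
  data.frame(effect = co$effect, statistic = co$t^2, df1 = 1L, df2 = co$df,
             p = co$p)
}

#' Pooled group mean
#'
#' n-weighted mean of subgroup means, as used to pool gender subgroups into
#' cohort totals in participant-characteristic tables.
#'
#' @param means numeric vector of subgroup means.
#' @param ns vector of subgroup sizes (all > 0).
#' @return The pooled mean.
#' @export
#' @examples
#' pooled_group_mean(c(166.8, 175.2), c(7, 8))  # 171.28
pooled_group_mean <- function(means, ns) {
  if (!length(means)) stop_exerstep("UndefinedMean", "no subgroups supplied")
  if (length(means) != length(ns) || any(ns <= 0) || any(!is.finite(ns))) {
    stop_exerstep("ConfigError", "each subgroup needs a positive n")
  }
  sum(means * ns) / sum(ns)
}
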