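# Independent oracles and fixture builders shared across the suite.

# Exhaustive per-frame threshold scan over the horizontal speed series: the
# naive reading of the step definition, kept deliberately loop-based and
# separate from the package's vectorized segmentation.
oracle_step_scan <- function(xyz, rate, cfg) {
  kin <- exerstep:::horiz_kinematics(xyz, rate, cfg$filter_cutoff)
  sp <- kin$speed
  sp[is.na(sp)] <- 0
  n <- length(sp)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (sp[i] >= cfg$stationary_speed) {
      j <- i
      while (j < n && sp[j + 1L] >= cfg$stationary_speed) j <- j + 1L
      size <- sqrt((kin$x[j] - kin$x[i])^2 + (kin$y[j] - kin$y[i])^2)
      if ((j - i) / rate >= cfg$min_duration && size >= cfg$min_displacement) {
        out[[length(out) + 1L]] <- data.frame(
          start = (i - 1L) / rate, end = (j - 1L) / rate, size = size)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(start = numeric(), end = numeric(), size = numeric()))
  }
  do.call(rbind, out)
}

# Naive crossing scan for arm lifts (frame loop with an up/down state).
oracle_lift_scan <- function(wrist_z, head_z, rate, hyst = 0.02, min_dur = 0.1) {
  state <- 0L
  start <- NA_real_
  out <- list()
  for (i in seq_along(wrist_z)) {
    t <- (i - 1L) / rate
    if (state == 0L && !is.na(wrist_z[i]) && wrist_z[i] > head_z[i]) {
      state <- 1L; start <- t
    } else if (state == 1L &&
                 (is.na(wrist_z[i]) || wrist_z[i] < head_z[i] - hyst)) {
      if (t - start >= min_dur) {
        out[[length(out) + 1L]] <- data.frame(start = start, end = t)
      }
      state <- 0L
    }
  }
  if (state == 1L) {
    t <- (length(wrist_z) - 1L) / rate
    if (t - start >= min_dur) out[[length(out) + 1L]] <- data.frame(start = start, end = t)
  }
  if (!length(out)) return(data.frame(start = numeric(), end = numeric()))
  do.call(rbind, out)
}

# Random short trajectory: plateaus alternating with moves of random size
# and duration straddling the detection thresholds. Returns the xyz matrix
# plus the commanded move list.
random_burst_trajectory <- function(rate = 120, n_moves = 5, noise = 0) {
  xyz <- matrix(0, 0, 3)
  x <- 0
  moves <- list()
  t <- 0
  for (k in seq_len(n_moves + 1L)) {
    hold <- round(runif(1, 0.3, 0.8) * rate)
    xyz <- rbind(xyz, matrix(rep(c(x, 0, 0), each = hold), ncol = 3))
    t <- t + hold / rate
    if (k <= n_moves) {
      d <- sample(c(-1, 1), 1) * runif(1, 0.01, 0.35)
      dur <- runif(1, 0.02, 0.6)
      nfr <- max(2L, round(dur * rate))
      tau <- seq_len(nfr) / nfr
      prof <- x + d * exerstep:::mj_pos(tau)
      xyz <- rbind(xyz, cbind(prof, 0, 0))
      moves[[k]] <- data.frame(start = t, size = abs(d), dur = nfr / rate)
      t <- t + nfr / rate
      x <- x + d
    }
  }
  if (noise > 0) xyz <- xyz + rnorm(length(xyz), 0, noise)
  list(xyz = unname(xyz), moves = do.call(rbind, moves))
}

# Minimal recording: one named marker following a given xyz matrix, all
# other requested markers static at the origin.
recording_with <- function(marker, xyz, rate = 120, extra_static = character()) {
  n <- nrow(xyz)
  mk <- unique(c(marker, extra_static))
  pos <- array(0, dim = c(n, length(mk), 3L), dimnames = list(NULL, mk, NULL))
  pos[, marker, ] <- xyz
  trial_recording(pos, rate = rate)
}

# Greedy interval matching (by midpoint proximity + overlap); returns counts
# for F1 computation.
match_events <- function(det, gt, tol = 0.15) {
  used <- rep(FALSE, nrow(gt))
  tp <- 0L
  if (nrow(det)) for (i in seq_len(nrow(det))) {
    best <- NA_integer_; bestov <- 0
    for (j in seq_len(nrow(gt))) {
      if (used[j]) next
      ov <- min(det$end[i], gt$end[j]) - max(det$start[i], gt$start[j])
      if (ov > bestov) { best <- j; bestov <- ov }
    }
    if (!is.na(best) && bestov > 0) { used[best] <- TRUE; tp <- tp + 1L }
  }
  c(tp = tp, fp = nrow(det) - tp, fn = nrow(gt) - tp)
}

quick_cohort_overrides <- list(trial_duration = 30, chickens_per_trial = 3)
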