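# Minimum-jerk point-to-point profile, the standard smooth model for human
# reaching and stepping. s(tau) runs 0 -> 1 over tau in [0,1] with zero
# velocity and acceleration at both ends; peak speed is 1.875 * d / T.

mj_pos <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  tau^3 * (10 - 15 * tau + 6 * tau^2)
}

mj_vel <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  30 * tau^2 * (1 - tau)^2
}

# Earliest tau in (0, 0.5] at which a minimum-jerk move of size `d` over
# duration `T` reaches speed `v`; NA if the peak speed never reaches v.
mj_speed_crossing <- function(d, T, v) {
  peak <- 1.875 * abs(d) / T
  if (peak <= v) return(NA_real_)
  f <- function(tau) (abs(d) / T) * mj_vel(tau) - v
  stats::uniroot(f, c(1e-9, 0.5), tol = 1e-10)$root
}

# Threshold-equivalent boundaries of a commanded minimum-jerk step: the
# interval on which the ideal (noise-free) profile moves faster than
# `v_thr`, plus the displacement accumulated inside it. This is what an
# ideal velocity-threshold detector observes, and is what the simulator
# records as ground truth.
mj_threshold_interval <- function(start, duration, displacement, v_thr) {
  tau <- mj_speed_crossing(displacement, duration, v_thr)
  if (is.na(tau)) return(NULL)
  list(
    start = start + tau * duration,
    end = start + (1 - tau) * duration,
    size = abs(displacement) * (mj_pos(1 - tau) - mj_pos(tau))
  )
}
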