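# Shared fixtures, all built in code.

# A noise-free default trial (cached: several files reuse it).
quiet_trial <- function(n_samples = 100L) {
  generate_trial(noise_sd = 0, seed = 1L, n_samples = n_samples)
}

# A synthetic trial whose ankle angle rises linearly through stance (so the
# spring length is monotone over [15%, 60%]), then plantarflexes after toe
# off.  Knee/hip flat, moments zero unless supplied.
monotone_trial <- function(n = 80L, ankle_peak = 0.25,
                           ankle_moment = NULL) {
  s <- seq(0, 1.12, length.out = n)
  ankle <- ifelse(s <= 1, ankle_peak * s, ankle_peak - 3 * (s - 1))
  if (is.null(ankle_moment)) ankle_moment <- numeric(n)
  gait_trial(
    time = s * 0.65, stance_fraction = s,
    ankle_angle = ankle, knee_angle = rep(0.1, n), hip_angle = rep(0.1, n),
    ankle_moment = ankle_moment, knee_moment = numeric(n),
    hip_moment = numeric(n),
    side = "left", subject_mass = 87.6, subject_height = 1.86
  )
}

# Minimal muscle rows for solver/energetics unit tests.  Single-joint
# actuators with constant moment arms by default.
toy_muscles <- function(n = 2L, ankle_r0 = c(0.05, 0.04, -0.04),
                        f_max = c(3000, 1500, 1200), side = "left") {
  m <- data.frame(
    side = side,
    name = paste0("m", seq_len(n)),
    f_max = f_max[seq_len(n)],
    l_opt = 0.06,
    tendon_slack = 0.25,
    v_max = 10,
    pennation = 0,
    fast_twitch_fraction = 0.5,
    ankle_r0 = ankle_r0[seq_len(n)], ankle_r1 = 0,
    knee_r0 = NA_real_, knee_r1 = NA_real_,
    hip_r0 = NA_real_, hip_r1 = NA_real_
  )
  m$muscle_mass <- m$f_max / 2.5e5 * m$l_opt * 1059.7
  class(m) <- c("muscle_set", "data.frame")
  m
}

# Optimal-length isometric state vectors for n muscles.
isometric_states <- function(n, activation = NULL) {
  list(
    norm_fiber_length = rep(1, n),
    norm_fiber_velocity = rep(0, n)
  )
}

# Dense grid search oracle for the 2-muscle, ankle-only static optimization
# (step 1e-3 over the activation square), on the full penalized objective.
# Meaningful only on well-conditioned instances: the lattice argmin tracks
# the true minimizer to O(step) only when reserve_weight * (gain * arm)^2
# is of order one, so oracle tests use weak muscles and unit reserve weight
# (the solver path is identical for any weight).
grid_search_2muscle <- function(required_ankle, gains, arms,
                                reserve_weight = 1, step = 1e-3) {
  a <- seq(0, 1, by = step)
  obj1 <- a^2
  resid <- required_ankle - outer(a * gains[1L] * arms[1L], a * gains[2L] * arms[2L], "+")
  total <- outer(obj1, obj1, "+") + reserve_weight * resid^2
  idx <- arrayInd(which.min(total), dim(total))
  c(a[idx[1L]], a[idx[2L]])
}
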