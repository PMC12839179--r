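#' Construct a stance-phase gait trial
#'
#' A `gait_trial` holds one foot contact: uniformly sampled time, the stance
#' coordinate (0 at heel strike, 1 at toe off, extended past 1 to maximum
#' plantarflexion), sagittal joint angles (ankle dorsiflexion-positive, knee
#' and hip flexion-positive, radians), net sagittal joint moments (ankle
#' plantarflexion-positive, knee and hip extension-positive, N*m), the side,
#' subject anthropometry, and the event indices (heel strike, foot flat at
#' 15\% of stance, toe off, maximum plantarflexion).
#'
#' @param time Numeric vector of sample times [s], strictly increasing.
#' @param stance_fraction Numeric vector, non-decreasing, 0 at heel strike
#'   and 1 at toe off.
#' @param ankle_angle,knee_angle,hip_angle Joint angles [rad].
#' @param ankle_moment,knee_moment,hip_moment Net joint moments [N*m].
#' @param side `"left"` or `"right"`.
#' @param subject_mass Body mass [kg].
#' @param subject_height Body height [m].
#' @return An object of class `gait_trial`.
#' @export
gait_trial <- function(time, stance_fraction, ankle_angle, knee_angle,
                       hip_angle, ankle_moment, knee_moment, hip_moment,
                       side = c("left", "right"),
                       subject_mass, subject_height) {
  side <- match.arg(side)
  n <- length(time)
  lens <- lengths(list(stance_fraction, ankle_angle, knee_angle, hip_angle,
                       ankle_moment, knee_moment, hip_moment))
  if (any(lens != n)) {
    stop_invalid("all trial series must have the same length as `time`")
  }
  events <- c(
    heel_strike = 1L,
    foot_flat = which(stance_fraction >= 0.15)[1L],
    toe_off = which(stance_fraction >= 1)[1L],
    max_plantarflexion = NA_integer_
  )
  if (is.na(events[["foot_flat"]]) || is.na(events[["toe_off"]])) {
    stop_invalid("trial must cover stance fractions 0.15 and 1.0")
  }
  post <- events[["toe_off"]]:n
  events[["max_plantarflexion"]] <- post[which.min(ankle_angle[post])]
  trial <- structure(
    list(
      time = time, stance_fraction = stance_fraction,
      ankle_angle = ankle_angle, knee_angle = knee_angle,
      hip_angle = hip_angle,
      ankle_moment = ankle_moment, knee_moment = knee_moment,
      hip_moment = hip_moment,
      side = side, subject_mass = subject_mass,
      subject_height = subject_height, events = events
    ),
    class = "gait_trial"
  )
  validate_gait_trial(trial)
}

validate_gait_trial <- function(trial) {
  with(trial, {
    if (any(diff(time) <= 0)) stop_invalid("time must be strictly increasing")
    if (any(diff(stance_fraction) < 0)) {
      stop_invalid("stance_fraction must be non-decreasing")
    }
    ev <- events
    if (!(ev[["heel_strike"]] < ev[["foot_flat"]] &&
          ev[["foot_flat"]] < ev[["toe_off"]] &&
          ev[["toe_off"]] < ev[["max_plantarflexion"]])) {
      stop_invalid("events must be ordered heel strike < foot flat < toe off < max plantarflexion")
    }
    ang <- c(ankle_angle, knee_angle, hip_angle)
    if (any(abs(ang) > pi / 2)) stop_invalid("joint angles must lie within +/- pi/2")
    if (subject_mass <= 0 || subject_height <= 0) {
      stop_invalid("subject mass and height must be positive")
    }
  })
  trial
}

#' Generate one synthetic stance-phase gait trial
#'
#' Draws one foot contact from the package's normative stance waveforms.
#' The ankle angle shows a brief plantarflexion dip after heel strike,
#' progressive dorsiflexion to a late-stance peak and rapid plantarflexion
#' through toe-off; the ankle net moment is a single-peaked plantarflexion
#' curve peaking in late stance.  Trial-to-trial variability is modeled per
#' waveform channel as a multiplicative amplitude factor `~ Normal(1,
#' noise_sd)` and an additive phase shift `~ Normal(0, noise_sd *
#' stance_duration / 10)` seconds.  Identical arguments with an identical
#' seed give bit-identical trials.
#'
#' @param speed Walking speed [m/s]; scales the net joint moments linearly
#'   around the 1.25 m/s normative curves.
#' @param stance_duration Stance time from heel strike to toe off [s].
#' @param subject_mass Body mass [kg] (net moments scale linearly).
#' @param subject_height Body height [m].
#' @param noise_sd Fractional trial-to-trial variability (0 disables noise).
#' @param seed Integer seed for the trial's noise draws.
#' @param n_samples Number of samples covering heel strike through maximum
#'   plantarflexion (default 100, the equivalent of 100 Hz capture at a
#'   stance time of order 1 s).
#' @param side `"left"` or `"right"` label.
#' @return A [gait_trial()].
#' @examples
#' trial <- generate_trial(noise_sd = 0, seed = 1)
#' trial
#' @export
generate_trial <- function(speed = 1.25, stance_duration = 0.65,
                           subject_mass = 87.6, subject_height = 1.86,
                           noise_sd = 0.005, seed = 1L, n_samples = 100L,
                           side = c("left", "right")) {
  side <- match.arg(side)
  if (stance_duration <= 0) stop_invalid("stance_duration must be positive")
  if (n_samples < 50) stop_invalid("n_samples must be at least 50")
  if (noise_sd < 0) stop_invalid("noise_sd must be non-negative")

  s <- seq(0, STANCE_TAIL_END, length.out = n_samples)
  time <- s * stance_duration
  channels <- gait_channels()

  draws <- with_seed(seed, {
    lapply(channels, function(ch) {
      list(amp = stats::rnorm(1, 1, noise_sd),
           phase = stats::rnorm(1, 0, noise_sd * stance_duration / 10))
    })
  })
  if (noise_sd == 0) {
    draws <- lapply(draws, function(d) list(amp = 1, phase = 0))
  }

  eval_channel <- function(name) {
    d <- draws[[name]]
    channels[[name]](s - d$phase / stance_duration) * d$amp
  }

  moment_scale <- subject_mass * speed / 1.25
  gait_trial(
    time = time,
    stance_fraction = s,
    ankle_angle = eval_channel("ankle_angle"),
    knee_angle = eval_channel("knee_angle"),
    hip_angle = eval_channel("hip_angle"),
    ankle_moment = eval_channel("ankle_moment") * moment_scale,
    knee_moment = eval_channel("knee_moment") * moment_scale,
    hip_moment = eval_channel("hip_moment") * moment_scale,
    side = side,
    subject_mass = subject_mass,
    subject_height = subject_height
  )
}

#' Generate a balanced cohort of foot contacts
#'
#' Returns `n_contacts` trials with sides alternating left/right (exactly
#' balanced), each with an independent noise draw from the seeded stream.
#' The default of 10 contacts (5 left, 5 right) mirrors a typical overground
#' collection protocol for a single subject.
#'
#' @param n_contacts Even number of foot contacts (>= 2).
#' @param speed,stance_duration,subject_mass,subject_height,noise_sd,n_samples
#'   Passed to [generate_trial()].
#' @param seed Master seed; each trial draws from a named substream.
#' @return A list of [gait_trial()] objects.
#' @export
generate_cohort <- function(n_contacts = 10L, speed = 1.25,
                            stance_duration = 0.65, subject_mass = 87.6,
                            subject_height = 1.86, noise_sd = 0.005,
                            seed = 1L, n_samples = 100L) {
  if (n_contacts < 2 || n_contacts %% 2 != 0) {
    stop_invalid("n_contacts must be even and at least 2")
  }
  lapply(seq_len(n_contacts), function(i) {
    generate_trial(
      speed = speed, stance_duration = stance_duration,
      subject_mass = subject_mass, subject_height = subject_height,
      noise_sd = noise_sd,
      seed = substream_seed(seed, paste0("trial", i)),
      n_samples = n_samples,
      side = if (i %% 2 == 1) "left" else "right"
    )
  })
}

#' Indices of the simulation window of a trial
#'
#' The analysis window runs from 15\% of stance (foot flat) to the maximum
#' plantarflexion angle after toe-off.
#'
#' @param trial A [gait_trial()].
#' @return Integer vector of sample indices.
#' @export
simulation_window <- function(trial) {
  trial$events[["foot_flat"]]:trial$events[["max_plantarflexion"]]
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf(
    "<gait_trial> %s foot contact: %d samples, %.3f s stance, subject %.1f kg / %.2f m\n",
    x$side, length(x$time),
    x$time[x$events[["toe_off"]]] - x$time[x$events[["heel_strike"]]],
    x$subject_mass, x$subject_height
  ))
  cat(sprintf(
    "  events [sample]: heel strike %d, foot flat %d, toe off %d, max plantarflexion %d\n",
    x$events[["heel_strike"]], x$events[["foot_flat"]],
    x$events[["toe_off"]], x$events[["max_plantarflexion"]]
  ))
  invisible(x)
}

#' @export
as.data.frame.gait_trial <- function(x, ...) {
  data.frame(
    time = x$time, stance_fraction = x$stance_fraction,
    ankle_angle = x$ankle_angle, knee_angle = x$knee_angle,
    hip_angle = x$hip_angle,
    ankle_moment = x$ankle_moment, knee_moment = x$knee_moment,
    hip_moment = x$hip_moment
  )
}
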