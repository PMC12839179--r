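#' Passive exoskeleton attachment geometry
#'
#' The exoskeleton is a foot bracket and a posterior shank bracket hinged at
#' the ankle, with a tension-only spring strung between an attachment on the
#' posterior foot bracket and one on the posterior-superior shank bracket.
#' Because the bracket hinge is constrained to follow the ankle angle, the
#' straight-line spring length follows from the law of cosines on the two
#' attachment arms, with included angle `attach_offset_angle + ankle_angle`
#' (dorsiflexion-positive, so dorsiflexion stretches the spring).
#'
#' @param shank_attach_r Distance from the hinge to the shank-bracket
#'   attachment [m].
#' @param foot_attach_r Distance from the hinge to the foot-bracket
#'   attachment [m].
#' @param attach_offset_angle Included angle between the two attachment arms
#'   at neutral ankle angle [rad]; the default keeps the spring posterior to
#'   the hinge throughout stance.
#' @param bracket_mass_foot,bracket_mass_shank Bracket masses [kg].
#' @param mass_lever_foot,mass_lever_shank Lever arms of the bracket centres
#'   of mass about the ankle and knee respectively [m], used by the
#'   quasi-static added-mass moment model.
#' @return An object of class `exo_geometry`.
#' @export
exo_geometry <- function(shank_attach_r = 0.30, foot_attach_r = 0.15,
                         attach_offset_angle = 1.75,
                         bracket_mass_foot = 1.2, bracket_mass_shank = 0.8,
                         mass_lever_foot = 0.18, mass_lever_shank = 0.06) {
  if (shank_attach_r <= 0 || foot_attach_r <= 0) {
    stop_invalid("attachment radii must be positive")
  }
  if (bracket_mass_foot < 0 || bracket_mass_shank < 0) {
    stop_invalid("bracket masses must be non-negative")
  }
  structure(
    list(
      shank_attach_r = shank_attach_r, foot_attach_r = foot_attach_r,
      attach_offset_angle = attach_offset_angle,
      bracket_mass_foot = bracket_mass_foot,
      bracket_mass_shank = bracket_mass_shank,
      mass_lever_foot = mass_lever_foot,
      mass_lever_shank = mass_lever_shank
    ),
    class = "exo_geometry"
  )
}

#' One exoskeleton setting of the parametric sweep
#'
#' @param stiffness_k Spring stiffness [N/m].
#' @param timing_tau Actuation timing [\% of stance] at which the spring
#'   first engages.
#' @param resting_length_L0 Derived spring resting length [m] (may be `NA`
#'   until bound to a trial with [resting_length_for_timing()]).
#' @param engaged Logical; `FALSE` models the worn-but-never-actuated
#'   exoskeleton (spring permanently slack).
#' @return An object of class `exo_setting`.
#' @export
exo_setting <- function(stiffness_k, timing_tau, resting_length_L0 = NA_real_,
                        engaged = TRUE) {
  if (stiffness_k <= 0) stop_invalid("stiffness must be positive")
  if (!is.na(resting_length_L0) && resting_length_L0 <= 0) {
    stop_invalid("resting length must be positive")
  }
  structure(
    list(stiffness_k = stiffness_k, timing_tau = timing_tau,
         resting_length_L0 = resting_length_L0, engaged = engaged),
    class = "exo_setting"
  )
}

#' Spring length at a given ankle angle
#'
#' Law of cosines on the two attachment arms with included angle
#' `attach_offset_angle + ankle_angle`.
#'
#' @param ankle_angle Ankle angle [rad], dorsiflexion positive (vectorized).
#' @param geometry An [exo_geometry()].
#' @return Spring length(s) [m].
#' @export
spring_length <- function(ankle_angle, geometry) {
  r1 <- geometry$shank_attach_r
  r2 <- geometry$foot_attach_r
  gam <- geometry$attach_offset_angle + ankle_angle
  sqrt(pmax(r1^2 + r2^2 - 2 * r1 * r2 * cos(gam), 0))
}

#' Perpendicular moment arm of the spring about the ankle hinge
#'
#' Equal to dL/d(ankle angle) of [spring_length()]; positive values mean
#' spring tension produces a plantarflexion moment (spring posterior to the
#' hinge).
#'
#' @inheritParams spring_length
#' @return Moment arm(s) [m].
#' @export
spring_moment_arm <- function(ankle_angle, geometry) {
  r1 <- geometry$shank_attach_r
  r2 <- geometry$foot_attach_r
  gam <- geometry$attach_offset_angle + ankle_angle
  len <- spring_length(ankle_angle, geometry)
  ifelse(len > 0, r1 * r2 * sin(gam) / len, 0)
}

#' Spring resting length realizing an actuation timing
#'
#' The physical delay device holds the spring slack until a set point in
#' stance; computationally the same effect is a resting length equal to the
#' spring length at the first sample at or past `tau` percent of stance, so
#' that the spring first engages no earlier than `tau`.  Longer resting
#' lengths correspond to later actuation timings whenever spring length is
#' non-decreasing over the timing range.
#'
#' @param trial A [gait_trial()] supplying the (pre-computed) ankle
#'   kinematics.
#' @param geometry An [exo_geometry()].
#' @param tau Actuation timing [\% of stance] in `[15, 60]`.
#' @return Resting length [m].
#' @export
resting_length_for_timing <- function(trial, geometry, tau) {
  if (tau < 15 || tau > 60) {
    stop_invalid("tau must lie in [15, 60] %% of stance, got %g", tau)
  }
  idx <- which(trial$stance_fraction >= tau / 100)[1L]
  if (is.na(idx)) {
    stop_invalid("trial does not cover %g%% of stance", tau)
  }
  spring_length(trial$ankle_angle[idx], geometry)
}

#' Tension-only spring force
#'
#' The spring acts through a cable, which cannot push: force is
#' `k * (length - L0)` when stretched past the resting length and exactly
#' zero otherwise (including at `length == L0`).
#'
#' @param length Current spring length(s) [m].
#' @param L0 Resting length [m].
#' @param k Stiffness [N/m].
#' @return Force(s) [N], non-negative.
#' @export
spring_force <- function(length, L0, k) {
  if (k <= 0) stop_invalid("stiffness must be positive")
  if (L0 <= 0) stop_invalid("resting length must be positive")
  ifelse(length > L0, k * (length - L0), 0)
}

#' Plantarflexion torque of the spring about the ankle
#'
#' @param ankle_angle Ankle angle(s) [rad].
#' @param force Spring tension(s) [N], non-negative.
#' @param geometry An [exo_geometry()].
#' @return Torque(s) [N*m], plantarflexion positive.
#' @export
spring_ankle_torque <- function(ankle_angle, force, geometry) {
  if (any(force < 0)) stop_invalid("spring force must be non-negative")
  force * spring_moment_arm(ankle_angle, geometry)
}

#' Elastic energy stored in the spring
#'
#' @inheritParams spring_force
#' @return Stored energy [J]; path-independent, zero when slack.
#' @export
spring_energy <- function(length, L0, k) {
  if (k <= 0) stop_invalid("stiffness must be positive")
  if (L0 <= 0) stop_invalid("resting length must be positive")
  0.5 * k * pmax(length - L0, 0)^2
}

#' Quasi-static added-mass moment adjustments of the bracket hardware
#'
#' Gravitational loading of the worn hardware, point-mass-on-lever model.
#' The ankle support moment carries the weight of the foot bracket (lever
#' `mass_lever_foot`, orientation factor `cos(ankle angle)` for the foot
#' segment) and of the shank bracket, which sits above the ankle and bears
#' down through the same forefoot support lever (orientation factor
#' `cos(knee angle)` for the shank segment).  The knee carries the shank
#' bracket on its own lever `mass_lever_shank`.  Inertial terms are
#' neglected (quasi-static model); zero masses give identically zero
#' adjustment.
#'
#' @param trial A [gait_trial()].
#' @param geometry An [exo_geometry()].
#' @return A data frame with columns `ankle`, `knee`, `hip` [N*m], one row
#'   per trial sample, in each joint's positive-moment convention.
#' @export
added_mass_moments <- function(trial, geometry) {
  n <- length(trial$time)
  data.frame(
    ankle = GRAVITY * geometry$mass_lever_foot *
      (geometry$bracket_mass_foot * cos(trial$ankle_angle) +
         geometry$bracket_mass_shank * cos(trial$knee_angle)),
    knee = geometry$bracket_mass_shank * GRAVITY *
      geometry$mass_lever_shank * cos(trial$knee_angle),
    hip = numeric(n)
  )
}

#' @export
print.exo_geometry <- function(x, ...) {
  cat(sprintf(
    "<exo_geometry> arms %.3f / %.3f m, offset %.3f rad; brackets %.2f + %.2f kg\n",
    x$shank_attach_r, x$foot_attach_r, x$attach_offset_angle,
    x$bracket_mass_foot, x$bracket_mass_shank
  ))
  invisible(x)
}

#' @export
print.exo_setting <- function(x, ...) {
  cat(sprintf(
    "<exo_setting> k = %.0f N/m, tau = %.0f%% of stance, L0 = %s m%s\n",
    x$stiffness_k, x$timing_tau,
    if (is.na(x$resting_length_L0)) "<unbound>" else
      sprintf("%.4f", x$resting_length_L0),
    if (x$engaged) "" else " (never engaged)"
  ))
  invisible(x)
}
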