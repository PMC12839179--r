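# Normative stance-phase waveform shapes.
#
# The stance coordinate s runs from 0 (heel strike) through 1 (toe off) and
# on to STANCE_TAIL_END (maximum plantarflexion after toe-off), so that the
# whole simulation window lives in one coordinate.  The shapes are fixed
# low-order smooth bases (Gaussian bumps and logistic ramps) whose
# landmarks follow adult overground walking, stylized in one deliberate
# respect: the dorsiflexion progression of the shank over the planted foot
# is concentrated into a brisk second-rocker rise just after foot flat
# (15-20% of stance), after which dorsiflexion holds a gently receding
# plateau until push-off.  This front-loads the ankle excursion available
# to a stance-phase spring: an actuator engaged at 15% of stance harvests
# nearly the whole excursion, while later engagements find most of it
# already spent — the kinematic mechanism by which actuation timing
# discriminates in this model.  The ankle net moment is a single-peaked
# plantarflexion curve peaking in late stance with a modest mid-stance
# shoulder.  Only the waveform class matters for the parametric sweep, not
# any one subject's exact curves; see the methods vignette.

# Stance coordinate at which the post-toe-off tail ends (maximum
# plantarflexion).  The generated trial's last sample sits here.
STANCE_TAIL_END <- 1.12

gauss_bump <- function(s, center, width) exp(-((s - center) / width)^2)

logistic_ramp <- function(s, center, width) 1 / (1 + exp(-(s - center) / width))

# Smooth cut-off that takes the net moments to zero shortly after toe-off
# (the foot is airborne; residual net moments are negligible).
post_toeoff_taper <- function(s) 1 / (1 + exp((s - 1.02) / 0.025))

# Sagittal ankle angle [rad], dorsiflexion positive: heel-strike
# plantarflexion dip, brisk dorsiflexion rise after foot flat, gently
# receding plateau, rapid plantarflexion through toe-off.
ankle_angle_shape <- function(s) {
  -0.08 * gauss_bump(s, 0.05, 0.055) +
    0.22 * logistic_ramp(s, 0.175, 0.012) *
      (1 - 0.2 * logistic_ramp(s, 0.62, 0.18)) -
    0.66 * logistic_ramp(s, 0.97, 0.05)
}

# Sagittal knee angle [rad], flexion positive.
knee_angle_shape <- function(s) {
  0.06 + 0.22 * gauss_bump(s, 0.22, 0.15) + 0.95 * gauss_bump(s, 1.35, 0.35)
}

# Sagittal hip angle [rad], flexion positive.
hip_angle_shape <- function(s) {
  0.45 * cos(2.6 * s) - 0.02
}

# Net sagittal joint moments per unit body mass [N*m/kg]:
# ankle plantarflexion positive, knee/hip extension positive.
ankle_moment_shape <- function(s) {
  w <- ifelse(s < 0.72, 0.20, 0.15)  # asymmetric main peak
  (1.45 * exp(-((s - 0.72) / w)^2) + 0.20 * gauss_bump(s, 0.33, 0.17)) *
    post_toeoff_taper(s)
}

knee_moment_shape <- function(s) {
  (0.50 * gauss_bump(s, 0.20, 0.13) - 0.15 * gauss_bump(s, 0.62, 0.17)) *
    post_toeoff_taper(s)
}

hip_moment_shape <- function(s) {
  (0.55 * gauss_bump(s, 0.12, 0.18) - 0.55 * gauss_bump(s, 0.80, 0.20)) *
    post_toeoff_taper(s)
}

# Channel registry: evaluation order is fixed because the per-trial noise
# draws (amplitude factor, phase shift) are consumed in this order.
gait_channels <- function() {
  list(
    ankle_angle = ankle_angle_shape,
    knee_angle = knee_angle_shape,
    hip_angle = hip_angle_shape,
    ankle_moment = ankle_moment_shape,
    knee_moment = knee_moment_shape,
    hip_moment = hip_moment_shape
  )
}
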