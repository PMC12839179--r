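# Hill-type muscle set and muscle-joint kinematics.
#
# Conventions (fixed package-wide): joint angles are ankle
# dorsiflexion-positive, knee flexion-positive, hip flexion-positive; joint
# moments are ankle plantarflexion-positive, knee extension-positive, hip
# extension-positive.  Moment arms are stored in the moment convention, so
# that musculotendon length obeys dL/d(theta) = +r for every joint (the
# classical r = -dL/d(theta) identity with the angle measured in the
# moment-positive sense).

# Reference anthropometry of the shipped parameter table.
MUSCLE_BASE_MASS <- 75.2    # kg
MUSCLE_BASE_HEIGHT <- 1.70  # m

# Specific tension [N/m^2] and muscle density [kg/m^3] used to derive
# muscle mass from f_max and l_opt (mass = f_max/sigma * l_opt * rho).
SPECIFIC_TENSION <- 2.5e5
MUSCLE_DENSITY <- 1059.7

JOINTS <- c("ankle", "knee", "hip")

#' Default sagittal lower-limb muscle set
#'
#' Returns the package's 8-muscle-per-leg sagittal set (soleus, medial and
#' lateral gastrocnemius, tibialis anterior, vasti, rectus femoris,
#' hamstrings, gluteus maximus), with maximal isometric forces scaled
#' linearly by body mass and optimal fiber/tendon lengths by height from
#' the shipped reference table, mirrored over both sides.  Muscle mass is
#' derived from the scaled `f_max` and `l_opt` through a declared specific
#' tension and density.
#'
#' @param subject_mass Body mass [kg].
#' @param subject_height Body height [m].
#' @return A data frame of class `muscle_set`, one row per muscle per side,
#'   with Hill-type parameters, energetic parameters, and moment-arm
#'   polynomial coefficients (`<joint>_r0`, `<joint>_r1`; `NA` when the
#'   muscle does not span the joint).
#' @export
default_muscle_set <- function(subject_mass = 87.6, subject_height = 1.86) {
  if (subject_mass <= 0 || subject_height <= 0) {
    stop_invalid("subject mass and height must be positive")
  }
  path <- system.file("extdata", "muscle_params.csv", package = "exosweep",
                      mustWork = TRUE)
  base <- utils::read.csv(path, comment.char = "#")
  base$f_max <- base$f_max * subject_mass / MUSCLE_BASE_MASS
  scale_len <- subject_height / MUSCLE_BASE_HEIGHT
  base$l_opt <- base$l_opt * scale_len
  base$tendon_slack <- base$tendon_slack * scale_len
  base$muscle_mass <- base$f_max / SPECIFIC_TENSION * base$l_opt *
    MUSCLE_DENSITY
  out <- rbind(
    cbind(side = "left", base, stringsAsFactors = FALSE),
    cbind(side = "right", base, stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  class(out) <- c("muscle_set", "data.frame")
  out
}

#' Moment arm of each muscle about each joint at given angles
#'
#' Evaluates the shipped moment-arm polynomials `r(theta) = r0 + r1*theta`.
#'
#' @param muscles A `muscle_set` (or a subset of its rows).
#' @param angles Named list/vector with `ankle`, `knee`, `hip` angles [rad];
#'   each may be a vector of time samples.
#' @return A list with one `n_samples x n_muscles` matrix per joint; zero
#'   where a muscle does not span the joint.
#' @export
moment_arm_matrix <- function(muscles, angles) {
  out <- lapply(JOINTS, function(j) {
    r0 <- muscles[[paste0(j, "_r0")]]
    r1 <- muscles[[paste0(j, "_r1")]]
    th <- angles[[j]]
    m <- outer(th, ifelse(is.na(r0), 0, r0), function(a, b) b) +
      outer(th, ifelse(is.na(r1), 0, r1))
    colnames(m) <- muscles$name
    m
  })
  names(out) <- JOINTS
  out
}

# Integral of the moment-arm polynomial from angle 0 to theta:
# musculotendon length change accumulated at one joint.
arm_integral <- function(r0, r1, theta) {
  if (is.na(r0)) return(numeric(length(theta)))
  r0 * theta + r1 / 2 * theta^2
}

#' Rigid-tendon muscle fiber kinematics along a trial
#'
#' Musculotendon length change is the sum over spanned joints of the
#' integral of the moment-arm polynomial from the neutral reference posture
#' (all joint angles zero, fiber at optimal length).  With a rigid tendon,
#' fiber length is `l_opt + dL / cos(pennation)`; fiber velocity (shortening
#' positive) comes from central differences of the sampled length series.
#'
#' @param trial A [gait_trial()].
#' @param muscles A `muscle_set` (typically one side's rows).
#' @return A list with matrices `norm_len` (fiber length / l_opt) and
#'   `norm_vel` (fiber shortening velocity / v_max), `n_samples x
#'   n_muscles`, plus `fiber_vel_mps` [m/s] used by the energetics work
#'   term.
#' @export
muscle_kinematics <- function(trial, muscles) {
  n <- length(trial$time)
  m <- nrow(muscles)
  angles <- list(ankle = trial$ankle_angle, knee = trial$knee_angle,
                 hip = trial$hip_angle)
  norm_len <- matrix(NA_real_, n, m, dimnames = list(NULL, muscles$name))
  fiber_vel <- norm_len
  for (i in seq_len(m)) {
    dl <- numeric(n)
    for (j in JOINTS) {
      dl <- dl + arm_integral(muscles[[paste0(j, "_r0")]][i],
                              muscles[[paste0(j, "_r1")]][i], angles[[j]])
    }
    lf <- muscles$l_opt[i] + dl / cos(muscles$pennation[i])
    if (any(lf <= 0)) {
      stop_invalid("degenerate geometry: non-positive fiber length in %s",
                   muscles$name[i])
    }
    norm_len[, i] <- lf / muscles$l_opt[i]
    fiber_vel[, i] <- -grad1(lf, trial$time)  # shortening positive
  }
  v_max_mps <- muscles$v_max * muscles$l_opt
  list(
    norm_len = norm_len,
    norm_vel = sweep(fiber_vel, 2, v_max_mps, "/"),
    fiber_vel_mps = fiber_vel
  )
}

#' Active force-length curve
#'
#' Gaussian-like curve with maximum value 1 at optimal fiber length.
#'
#' @param norm_len Fiber length / optimal fiber length.
#' @return Dimensionless force scale in (0, 1].
#' @export
force_length <- function(norm_len) {
  exp(-((norm_len - 1) / 0.45)^2)
}

#' Force-velocity curve
#'
#' Hill hyperbola on the concentric side (`f(0) = 1`, `f(1) = 0`, zero
#' beyond maximal shortening) and a smooth saturating eccentric branch
#' bounded by 1.5, continuous with matched slope at zero velocity.
#'
#' @param norm_vel Fiber velocity / v_max, shortening positive.
#' @return Dimensionless force scale in [0, 1.5].
#' @export
force_velocity <- function(norm_vel) {
  a_f <- 0.25
  ifelse(
    norm_vel >= 0,
    pmax(0, (1 - norm_vel)) / (1 + pmin(norm_vel, 1) / a_f),
    1.5 - 0.5 * exp((1 + 1 / a_f) / 0.5 * norm_vel)
  )
}

#' Passive fiber force curve
#'
#' Exponential passive elastic force, zero at and below optimal length and
#' reaching one maximal isometric force at 60\% passive strain.
#'
#' @param norm_len Fiber length / optimal fiber length.
#' @return Dimensionless passive force (>= 0).
#' @export
force_passive <- function(norm_len) {
  pmax(0, expm1(4 * (norm_len - 1) / 0.6) / expm1(4))
}

#' Hill-type musculotendon force
#'
#' `force = a * f_max * f_L * f_V * cos(pennation) + passive`, with the
#' passive term `f_max * f_P * cos(pennation)`.
#'
#' @param state List with `activation`, `norm_fiber_length`,
#'   `norm_fiber_velocity` (shortening positive).
#' @param params One row of a `muscle_set`.
#' @param include_passive Include the passive elastic term?
#' @return Force [N].
#' @export
muscle_force <- function(state, params, include_passive = TRUE) {
  a <- state$activation
  if (any(a < 0 | a > 1)) stop_invalid("activation must lie in [0, 1]")
  act <- a * params$f_max * force_length(state$norm_fiber_length) *
    force_velocity(state$norm_fiber_velocity) * cos(params$pennation)
  pas <- if (include_passive) {
    params$f_max * force_passive(state$norm_fiber_length) *
      cos(params$pennation)
  } else 0
  act + pas
}
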