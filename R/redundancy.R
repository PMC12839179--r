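# Muscle redundancy resolution by per-time-step static optimization.
#
# At each sample the required sagittal joint moments (net moments minus
# exoskeleton torque, plus added-mass adjustments) are distributed across
# the ipsilateral muscles by minimizing the sum of squared activations,
# with penalized reserve actuators at each joint guaranteeing feasibility:
#
#   minimize  sum(a^2) + w * sum(r^2)
#   s.t.      R %*% force(a) + r = required,   0 <= a <= 1
#
# Under the rigid-tendon model the muscle forces are affine in activation,
# so eliminating r leaves a strictly convex box-constrained quadratic
# program solved exactly by a primal active-set method.

#' Required joint moments after exoskeleton substitution
#'
#' The ankle requirement is the net plantarflexion moment minus the
#' exoskeleton's plantarflexion torque plus the added-mass adjustment;
#' knee and hip requirements are the net moments plus their adjustments.
#' Negative requirements pass through unchanged (antagonists must resist).
#'
#' @param trial A [gait_trial()].
#' @param exo_torque Plantarflexion torque series of the spring [N*m],
#'   same length as the trial (0 when no exoskeleton is worn).
#' @param mass_adjustment Data frame from [added_mass_moments()], or `NULL`
#'   for no adjustment.
#' @return A data frame with columns `ankle`, `knee`, `hip` [N*m].
#' @export
required_moments <- function(trial, exo_torque = 0,
                             mass_adjustment = NULL) {
  n <- length(trial$time)
  if (is.null(mass_adjustment)) {
    mass_adjustment <- data.frame(ankle = numeric(n), knee = numeric(n),
                                  hip = numeric(n))
  }
  data.frame(
    ankle = trial$ankle_moment - exo_torque + mass_adjustment$ankle,
    knee = trial$knee_moment + mass_adjustment$knee,
    hip = trial$hip_moment + mass_adjustment$hip
  )
}

# Exact primal active-set solver for
#   min 0.5 a' H a - f' a,  0 <= a <= 1,
# with H symmetric positive definite.  Classical monotone active-set
# iteration: solve the equality-constrained problem on the free variables,
# step toward it with ratio-test clamping (blocking variable joins the
# working set), and release the bound variable with the worst Lagrange
# multiplier when the subproblem is solved.  Finite for strictly convex H.
solve_box_qp <- function(H, f, max_iter = 500L, tol = 1e-10) {
  n <- length(f)
  a <- numeric(n)
  at_lo <- rep(TRUE, n)
  at_hi <- rep(FALSE, n)
  for (iter in seq_len(max_iter)) {
    free <- !(at_lo | at_hi)
    target <- ifelse(at_hi, 1, 0)
    if (any(free)) {
      rhs <- f[free]
      if (any(!free)) {
        rhs <- rhs - H[free, !free, drop = FALSE] %*% target[!free]
      }
      target[free] <- solve(H[free, free, drop = FALSE], rhs)
    }
    d <- target - a
    if (max(abs(d)) <= tol) {
      g <- drop(H %*% a) - f
      viol_lo <- at_lo & g < -tol  # lower-bound multiplier must be >= 0
      viol_hi <- at_hi & g > tol   # upper-bound multiplier must be >= 0
      if (!any(viol_lo) && !any(viol_hi)) {
        return(pmin(pmax(a, 0), 1))
      }
      score <- numeric(n)
      score[viol_lo] <- -g[viol_lo]
      score[viol_hi] <- g[viol_hi]
      j <- which.max(score)
      at_lo[j] <- FALSE
      at_hi[j] <- FALSE
    } else {
      alpha <- 1
      block <- 0L
      block_hi <- FALSE
      for (i in which(free)) {
        if (d[i] > tol) {
          s <- (1 - a[i]) / d[i]
          if (s < alpha) {
            alpha <- s; block <- i; block_hi <- TRUE
          }
        } else if (d[i] < -tol) {
          s <- -a[i] / d[i]
          if (s < alpha) {
            alpha <- s; block <- i; block_hi <- FALSE
          }
        }
      }
      a <- a + alpha * d
      if (block > 0L) {
        if (block_hi) {
          at_hi[block] <- TRUE
          a[block] <- 1
        } else {
          at_lo[block] <- TRUE
          a[block] <- 0
        }
      }
      a[at_lo] <- 0
      a[at_hi] <- 1
    }
  }
  stop_invalid("static optimization active-set solver did not converge")
}

#' Static optimization at a single time step
#'
#' Minimizes summed squared activations plus a quadratic reserve penalty
#' subject to sagittal moment balance at the ankle, knee and hip and
#' activation bounds `[0, 1]`.  Reserve actuators absorb any moment the
#' muscles cannot produce; a step is flagged infeasible when any reserve
#' magnitude exceeds `reserve_threshold`.
#'
#' @param required Named numeric vector (`ankle`, `knee`, `hip`) of required
#'   moments [N*m].
#' @param states List with numeric vectors `norm_fiber_length` and
#'   `norm_fiber_velocity` (one entry per muscle).
#' @param params A `muscle_set` subset (one row per muscle).
#' @param angles Named list/vector of joint angles [rad] at this step, used
#'   to evaluate the moment-arm polynomials.
#' @param reserve_weight Penalty weight on squared reserve moments.
#' @param reserve_threshold Reserve magnitude [N*m] above which the step is
#'   flagged infeasible.
#' @return A list with `activations`, `forces` [N], `reserves` [N*m],
#'   `objective` (sum of squared activations) and `feasible`.
#' @export
solve_static_optimization <- function(required, states, params, angles,
                                      reserve_weight = 1e3,
                                      reserve_threshold = 1.0) {
  m <- nrow(params)
  if (is.null(m) || m == 0L) stop_invalid("muscle set is empty")
  arms <- moment_arm_matrix(params, lapply(angles, function(x) x[1L]))
  R <- rbind(arms$ankle[1L, ], arms$knee[1L, ], arms$hip[1L, ])
  gain <- params$f_max * force_length(states$norm_fiber_length) *
    force_velocity(states$norm_fiber_velocity) * cos(params$pennation)
  passive <- params$f_max * force_passive(states$norm_fiber_length) *
    cos(params$pennation)
  C <- R * rep(gain, each = 3L)
  b <- as.numeric(required[JOINTS]) - drop(R %*% passive)
  H <- diag(2, m) + 2 * reserve_weight * crossprod(C)
  f <- 2 * reserve_weight * drop(crossprod(C, b))
  a <- solve_box_qp(H, f)
  reserves <- b - drop(C %*% a)
  list(
    activations = stats::setNames(a, params$name),
    forces = stats::setNames(a * gain + passive, params$name),
    reserves = stats::setNames(reserves, JOINTS),
    objective = sum(a^2),
    feasible = all(abs(reserves) <= reserve_threshold)
  )
}

# Precompute everything about one trial that is shared across exoskeleton
# settings: simulation window, fiber kinematics, per-step moment-arm and
# force-gain matrices, and the QP pieces (H, f) for zero exoskeleton torque.
# Per setting only the ankle requirement changes, which enters f linearly.
prepare_trial_context <- function(trial, muscles, geometry = NULL,
                                  reserve_weight = 1e3,
                                  reserve_threshold = 1.0) {
  side_muscles <- muscles[muscles$side == trial$side, , drop = FALSE]
  if (nrow(side_muscles) == 0L) stop_invalid("muscle set is empty")
  win <- simulation_window(trial)
  kin <- muscle_kinematics(trial, side_muscles)
  adj <- if (is.null(geometry)) NULL else added_mass_moments(trial, geometry)
  req <- required_moments(trial, exo_torque = 0, mass_adjustment = adj)
  angles <- list(ankle = trial$ankle_angle, knee = trial$knee_angle,
                 hip = trial$hip_angle)
  arms <- moment_arm_matrix(side_muscles, angles)
  m <- nrow(side_muscles)
  nw <- length(win)
  cosp <- cos(side_muscles$pennation)
  steps <- vector("list", nw)
  for (s in seq_len(nw)) {
    i <- win[s]
    gain <- side_muscles$f_max * force_length(kin$norm_len[i, ]) *
      force_velocity(kin$norm_vel[i, ]) * cosp
    passive <- side_muscles$f_max * force_passive(kin$norm_len[i, ]) * cosp
    R <- rbind(arms$ankle[i, ], arms$knee[i, ], arms$hip[i, ])
    C <- R * rep(gain, each = 3L)
    b <- c(req$ankle[i], req$knee[i], req$hip[i]) - drop(R %*% passive)
    steps[[s]] <- list(
      gain = gain, passive = passive, C = C, b = b,
      H = diag(2, m) + 2 * reserve_weight * crossprod(C),
      f0 = 2 * reserve_weight * drop(crossprod(C, b)),
      # f changes by -fc * exo_torque when the spring unloads the ankle
      fc = 2 * reserve_weight * C[1L, ]
    )
  }
  list(
    trial = trial, muscles = side_muscles, window = win, kin = kin,
    steps = steps, reserve_weight = reserve_weight,
    reserve_threshold = reserve_threshold,
    spring_len = if (is.null(geometry)) NULL else
      spring_length(trial$ankle_angle, geometry),
    spring_arm = if (is.null(geometry)) NULL else
      spring_moment_arm(trial$ankle_angle, geometry),
    geometry = geometry
  )
}

# Solve every step of a prepared context for a given exoskeleton torque
# series over the window (0 for baseline / never-engaged conditions).
solve_prepared <- function(ctx, exo_torque_window = NULL) {
  nw <- length(ctx$window)
  m <- nrow(ctx$muscles)
  if (is.null(exo_torque_window)) exo_torque_window <- numeric(nw)
  act <- matrix(NA_real_, nw, m, dimnames = list(NULL, ctx$muscles$name))
  forces <- act
  reserves <- matrix(NA_real_, nw, 3L, dimnames = list(NULL, JOINTS))
  for (s in seq_len(nw)) {
    st <- ctx$steps[[s]]
    f <- st$f0 - st$fc * exo_torque_window[s]
    a <- solve_box_qp(st$H, f)
    act[s, ] <- a
    forces[s, ] <- a * st$gain + st$passive
    b <- st$b
    b[1L] <- b[1L] - exo_torque_window[s]
    reserves[s, ] <- b - drop(st$C %*% a)
  }
  win <- ctx$window
  structure(
    list(
      time = ctx$trial$time[win],
      window = win,
      activations = act,
      forces = forces,
      reserves = reserves,
      objective = rowSums(act^2),
      feasible = apply(abs(reserves) <= ctx$reserve_threshold, 1L, all),
      norm_len = ctx$kin$norm_len[win, , drop = FALSE],
      norm_vel = ctx$kin$norm_vel[win, , drop = FALSE],
      fiber_vel_mps = ctx$kin$fiber_vel_mps[win, , drop = FALSE],
      exo_torque = exo_torque_window,
      muscles = ctx$muscles,
      side = ctx$trial$side,
      subject_mass = ctx$trial$subject_mass
    ),
    class = "activation_solution"
  )
}

# Exoskeleton torque over the window of a prepared context for one setting.
# The gravity-actuated delay device physically blocks energy loading before
# the actuation timing; computationally the spring force is zero at all
# samples before the first sample at or past tau, and follows the
# tension-only law k*(L - L0)+ afterwards.
exo_torque_window <- function(ctx, setting) {
  if (is.null(ctx$geometry) || is.null(setting) || !setting$engaged) {
    return(numeric(length(ctx$window)))
  }
  L0 <- setting$resting_length_L0
  if (is.na(L0)) {
    L0 <- resting_length_for_timing(ctx$trial, ctx$geometry,
                                    setting$timing_tau)
  }
  len <- ctx$spring_len[ctx$window]
  force <- spring_force(len, L0, setting$stiffness_k)
  sf <- ctx$trial$stance_fraction[ctx$window]
  force[sf < setting$timing_tau / 100] <- 0
  force * ctx$spring_arm[ctx$window]
}

#' Solve a whole trial under one exoskeleton condition
#'
#' Applies the per-step static optimization across the simulation window
#' (15\% of stance through maximum plantarflexion after toe-off), for the
#' ipsilateral leg's muscles only.  Three conditions are expressible:
#' baseline (`geometry = NULL`: no exoskeleton, no bracket mass), worn but
#' never actuated (`geometry` given, `setting = NULL`: bracket masses only),
#' and actuated (`geometry` and `setting` given; the spring's resting length
#' is derived from the trial's own kinematics when not already bound).
#'
#' @param trial A [gait_trial()].
#' @param muscles A `muscle_set` from [default_muscle_set()].
#' @param geometry An [exo_geometry()] or `NULL`.
#' @param setting An [exo_setting()] or `NULL`.
#' @param reserve_weight,reserve_threshold See
#'   [solve_static_optimization()].
#' @return An `activation_solution`: per-step activation, force and reserve
#'   series with fiber kinematics, over the simulation window.
#' @export
solve_trial <- function(trial, muscles, geometry = NULL, setting = NULL,
                        reserve_weight = 1e3, reserve_threshold = 1.0) {
  ctx <- prepare_trial_context(trial, muscles, geometry,
                               reserve_weight, reserve_threshold)
  solve_prepared(ctx, exo_torque_window(ctx, setting))
}

#' Export an activation solution as a time-series table
#'
#' Writes the per-step muscle activations and forces (one column per
#' muscle, prefixed `act_` / `force_`) as an OpenSim-style `.sto` table or
#' plain CSV, depending on the file extension.
#'
#' @param solution An `activation_solution` from [solve_trial()].
#' @param path Output path (`.sto`/`.mot` or `.csv`).
#' @export
write_solution <- function(solution, path) {
  df <- data.frame(
    time = solution$time,
    stats::setNames(as.data.frame(solution$activations),
                    paste0("act_", colnames(solution$activations))),
    stats::setNames(as.data.frame(solution$forces),
                    paste0("force_", colnames(solution$forces)))
  )
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    write_trial_csv(df, path)
  } else {
    write_sto(df, path, name = basename(path))
  }
  invisible(path)
}

#' @export
print.activation_solution <- function(x, ...) {
  cat(sprintf(
    "<activation_solution> %s side, %d steps x %d muscles; %d/%d steps feasible\n",
    x$side, nrow(x$activations), ncol(x$activations),
    sum(x$feasible), length(x$feasible)
  ))
  invisible(x)
}
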