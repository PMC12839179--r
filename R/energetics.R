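# Umberger-style muscle metabolic energetics.
#
# Metabolic rate per muscle is partitioned into activation+maintenance
# heat, shortening/lengthening heat and mechanical work, following the
# empirical model family of Umberger and colleagues.  The exact coefficient
# table shipped here (and the variant choices: eccentric mechanical work
# not credited, basal rate excluded, total rate clamped at zero) is
# documented in `umberger_constants()` and in the methods vignette; tests
# hand-evaluate the same table.

#' Coefficient table of the muscle energetics model
#'
#' All heat-rate coefficients are per kilogram of muscle mass.
#'
#' \describe{
#'   \item{h_am_slow / h_am_fast_slope}{Activation+maintenance heat rate
#'     `(h_am_slow + h_am_fast_slope * ft) * a^act_exponent` [W/kg], with
#'     `ft` the fast-twitch fraction.}
#'   \item{act_exponent}{Activation exponent 0.6 of the heat terms.}
#'   \item{vmax_st_divisor}{Maximal shortening velocity of slow fibers as
#'     `v_max / vmax_st_divisor`.}
#'   \item{alpha_short_st / alpha_short_ft}{Shortening-heat coefficients:
#'     `100 / v_max_st` and `153 / v_max` [W/kg per l_opt/s], combined by
#'     fiber-type fraction and scaled by `a^2`.}
#'   \item{alpha_length_factor}{Lengthening-heat coefficient as a fraction
#'     of the slow-fiber shortening coefficient, scaled by `a`.}
#'   \item{aerobic_scale}{Overall scale S applied to the heat terms
#'     (aerobic, steady-gait value 1.5).}
#' }
#'
#' Mechanical work rate is the contractile-element force times fiber
#' shortening velocity, with no credit for eccentric (lengthening) work;
#' the summed rate is clamped at zero and the basal rate is excluded.
#' For fiber lengths above optimal, the activation+maintenance and
#' shortening heats are scaled toward the active force-length curve
#' (`0.4 + 0.6 * f_L` for the former, `f_L` for the latter).
#'
#' @return Named list of coefficients.
#' @export
umberger_constants <- function() {
  list(
    h_am_slow = 25,          # W/kg at full activation, slow-twitch
    h_am_fast_slope = 128,   # additional W/kg per unit fast-twitch fraction
    act_exponent = 0.6,
    vmax_st_divisor = 2.5,
    alpha_short_st_numerator = 100,  # -> 100 / v_max_st  [W/kg per lopt/s]
    alpha_short_ft_numerator = 153,  # -> 153 / v_max
    alpha_length_factor = 0.3,       # * alpha_short_st, scaled by a
    aerobic_scale = 1.5
  )
}

#' Metabolic rate of one muscle
#'
#' Computes the Umberger-style metabolic power time series
#' `rate = muscle_mass * S * (h_AM + h_SL) + w_dot`, where `w_dot` is the
#' positive (shortening) contractile-element work rate.  Inactive samples
#' (`activation = 0`) cost nothing, and the rate is clamped at zero.
#'
#' @param activation Activation series in [0, 1].
#' @param norm_len Normalized fiber length series.
#' @param norm_vel Normalized fiber velocity series (shortening positive).
#' @param fiber_vel_mps Fiber shortening velocity [m/s].
#' @param params One row of a `muscle_set`.
#' @return Metabolic rate series [W], non-negative.
#' @export
metabolic_rate <- function(activation, norm_len, norm_vel, fiber_vel_mps,
                           params) {
  metabolic_rate_components(activation, norm_len, norm_vel, fiber_vel_mps,
                            params)$rate
}

#' Metabolic rate partitioned into its heat and work components
#'
#' Same model as [metabolic_rate()], returning the activation+maintenance
#' heat, shortening/lengthening heat (both in W, already scaled by muscle
#' mass and the aerobic factor) and the positive mechanical work rate
#' separately, together with their clamped sum.
#'
#' @inheritParams metabolic_rate
#' @return A list of numeric series `h_am_w`, `h_sl_w`, `w_dot` and `rate`
#'   [W].
#' @export
metabolic_rate_components <- function(activation, norm_len, norm_vel,
                                      fiber_vel_mps, params) {
  if (any(activation < 0 | activation > 1)) {
    stop_invalid("activation must lie in [0, 1]")
  }
  kc <- umberger_constants()
  ft <- params$fast_twitch_fraction
  a_h <- activation^kc$act_exponent

  # activation + maintenance heat [W/kg]
  h_am <- (kc$h_am_slow + kc$h_am_fast_slope * ft) * a_h

  # shortening / lengthening heat [W/kg]
  v_max_st <- params$v_max / kc$vmax_st_divisor
  alpha_st <- kc$alpha_short_st_numerator / v_max_st
  alpha_ft <- kc$alpha_short_ft_numerator / params$v_max
  v_lopt <- norm_vel * params$v_max  # fiber velocity in l_opt/s
  h_sl <- ifelse(
    v_lopt >= 0,
    (alpha_st * (1 - ft) + alpha_ft * ft) * v_lopt * activation^2,
    kc$alpha_length_factor * alpha_st * (-v_lopt) * activation
  )

  # above optimal length the heat rates scale toward the force-length curve
  fl <- force_length(norm_len)
  long <- norm_len > 1
  h_am[long] <- h_am[long] * (0.4 + 0.6 * fl[long])
  h_sl[long & v_lopt >= 0] <- h_sl[long & v_lopt >= 0] * fl[long & v_lopt >= 0]

  # positive mechanical work rate of the contractile element [W]
  f_ce <- activation * params$f_max * fl * force_velocity(norm_vel) *
    cos(params$pennation)
  w_dot <- pmax(f_ce * fiber_vel_mps, 0)

  scale <- params$muscle_mass * kc$aerobic_scale
  rate <- scale * (h_am + h_sl) + w_dot
  rate[activation == 0] <- 0
  list(
    h_am_w = scale * h_am,
    h_sl_w = scale * h_sl,
    w_dot = w_dot,
    rate = pmax(rate, 0)
  )
}

#' Trapezoidal integral of a metabolic rate series
#'
#' @param rate Metabolic rate series [W].
#' @param time Sample times [s], strictly increasing, same length.
#' @return Energy [J].
#' @export
integrate_energy <- function(rate, time) {
  if (length(rate) != length(time)) {
    stop_invalid("rate and time must have equal length")
  }
  if (any(diff(time) <= 0)) stop_invalid("time must be strictly increasing")
  trapz(time, rate)
}

#' Total metabolic energy normalized to body mass
#'
#' Sums the energies of the muscles ipsilateral to the foot contact (the
#' contralateral leg serves the swing phase and is excluded) and divides by
#' body mass.
#'
#' @param per_muscle Numeric vector of per-muscle energies [J].
#' @param muscle_side Character vector of sides, parallel to `per_muscle`.
#' @param side The trial's side (`"left"` or `"right"`).
#' @param subject_mass Body mass [kg].
#' @return A list of class `energy_result` with `per_muscle_energy` (the
#'   ipsilateral subset), `total_energy` [J] and `total_energy_per_kg`
#'   [J/kg].
#' @export
total_energy <- function(per_muscle, muscle_side, side, subject_mass) {
  if (subject_mass <= 0) stop_invalid("subject mass must be positive")
  ips <- muscle_side == side
  if (!any(ips)) {
    warning("no ipsilateral muscles; total energy is zero", call. = FALSE)
  }
  tot <- sum(per_muscle[ips])
  structure(
    list(
      per_muscle_energy = per_muscle[ips],
      total_energy = tot,
      total_energy_per_kg = tot / subject_mass,
      side = side,
      subject_mass = subject_mass
    ),
    class = "energy_result"
  )
}

#' Metabolic energy of a solved trial
#'
#' Evaluates [metabolic_rate()] for every muscle of an
#' [solve_trial()] solution, integrates over the simulation window, and
#' normalizes to body mass.
#'
#' @param solution An `activation_solution`.
#' @return An `energy_result` with per-muscle heat/work components
#'   (`components` data frame) and `total_energy_per_kg` [J/kg].
#' @export
trial_energy <- function(solution) {
  mus <- solution$muscles
  m <- nrow(mus)
  per <- numeric(m)
  comp <- data.frame(
    muscle = mus$name, side = mus$side,
    activation_maintenance_J = numeric(m),
    shortening_lengthening_J = numeric(m),
    work_J = numeric(m), total_J = numeric(m)
  )
  for (i in seq_len(m)) {
    parts <- metabolic_rate_components(
      solution$activations[, i], solution$norm_len[, i],
      solution$norm_vel[, i], solution$fiber_vel_mps[, i],
      mus[i, , drop = FALSE]
    )
    per[i] <- integrate_energy(parts$rate, solution$time)
    comp$activation_maintenance_J[i] <-
      integrate_energy(parts$h_am_w, solution$time)
    comp$shortening_lengthening_J[i] <-
      integrate_energy(parts$h_sl_w, solution$time)
    comp$work_J[i] <- integrate_energy(parts$w_dot, solution$time)
    comp$total_J[i] <- per[i]
  }
  names(per) <- mus$name
  res <- total_energy(per, mus$side, solution$side, solution$subject_mass)
  res$components <- comp
  res$window_time <- range(solution$time)
  res
}

#' Write a per-muscle energy report as CSV
#'
#' One row per muscle: side, heat components, mechanical work and total
#' energy [J] over the simulation window.
#'
#' @param result An `energy_result` from [trial_energy()].
#' @param path Output CSV path.
#' @export
write_energy_report <- function(result, path) {
  if (is.null(result$components)) {
    stop_invalid("energy result carries no component table")
  }
  utils::write.csv(result$components, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.energy_result <- function(x, ...) {
  cat(sprintf(
    "<energy_result> %s side: %.4g J total, %.4g J/kg over %d muscles\n",
    x$side, x$total_energy, x$total_energy_per_kg,
    length(x$per_muscle_energy)
  ))
  invisible(x)
}
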