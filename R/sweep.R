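# Stiffness x actuation-timing parametric sweep.

#' Build the stiffness x timing settings grid
#'
#' Cartesian product in stiffness-major ordering (stiffness varies slowest),
#' built by integer index so that the grid endpoints are exactly
#' representable.  The defaults reproduce the 25 stiffnesses (5.5-17.5 kN/m
#' in 0.5 kN/m steps) by 10 timings (15-60\% of stance in 5\% steps) = 250
#' settings.
#'
#' @param k_min,k_max,k_step Stiffness range and step [N/m].
#' @param tau_min,tau_max,tau_step Actuation-timing range and step
#'   [\% of stance].
#' @return A data frame with columns `stiffness_k` and `timing_tau`, one
#'   row per setting.
#' @export
build_grid <- function(k_min = 5500, k_max = 17500, k_step = 500,
                       tau_min = 15, tau_max = 60, tau_step = 5) {
  if (k_step <= 0 || tau_step <= 0) stop_invalid("grid steps must be positive")
  if (k_min > k_max || tau_min > tau_max) {
    stop_invalid("grid minima must not exceed maxima")
  }
  nk <- (k_max - k_min) / k_step
  nt <- (tau_max - tau_min) / tau_step
  if (abs(nk - round(nk)) > 1e-9 || abs(nt - round(nt)) > 1e-9) {
    stop_invalid("grid step must divide the range exactly")
  }
  ks <- k_min + k_step * 0:round(nk)
  taus <- tau_min + tau_step * 0:round(nt)
  out <- data.frame(
    stiffness_k = rep(ks, each = length(taus)),
    timing_tau = rep(taus, times = length(ks))
  )
  out
}

#' Run the full stiffness x timing sweep over a cohort
#'
#' For every (setting, foot contact) pair: derives the spring resting
#' length from that contact's own ankle kinematics, solves the static
#' optimization over the simulation window, and integrates muscle metabolic
#' energy to J/kg.  Also computes two reference conditions per contact:
#' baseline (no exoskeleton, no bracket mass) and worn-but-never-actuated
#' (bracket masses on, spring permanently slack).  The percent energy
#' change `100 * (E_setting - E_baseline) / E_baseline` is computed per
#' contact and averaged over contacts per grid cell.
#'
#' @param cohort List of [gait_trial()] objects.
#' @param grid Settings data frame from [build_grid()].
#' @param geometry An [exo_geometry()].
#' @param muscles A `muscle_set`.
#' @param reserve_weight,reserve_threshold See
#'   [solve_static_optimization()].
#' @param progress Print per-contact progress?
#' @return A list of class `sweep_result`: `grid` (per-cell mean/sd percent
#'   energy change, number of contacts, infeasible-step counts),
#'   `per_contact` (one row per simulation record), `baseline_per_contact`
#'   and `no_actuation_per_contact` [J/kg], and `n_simulations`.
#' @export
run_sweep <- function(cohort, grid, geometry = exo_geometry(),
                      muscles = NULL, reserve_weight = 1e3,
                      reserve_threshold = 1.0, progress = FALSE) {
  if (length(cohort) == 0L) stop_invalid("cohort is empty")
  if (is.null(muscles)) {
    muscles <- default_muscle_set(cohort[[1L]]$subject_mass,
                                  cohort[[1L]]$subject_height)
  }
  n_trial <- length(cohort)
  n_set <- nrow(grid)
  baseline <- numeric(n_trial)
  no_act <- numeric(n_trial)
  records <- vector("list", n_trial)
  for (t in seq_len(n_trial)) {
    trial <- cohort[[t]]
    ctx_base <- prepare_trial_context(trial, muscles, geometry = NULL,
                                      reserve_weight, reserve_threshold)
    baseline[t] <- trial_energy(solve_prepared(ctx_base))$total_energy_per_kg
    ctx_exo <- prepare_trial_context(trial, muscles, geometry,
                                     reserve_weight, reserve_threshold)
    no_act[t] <- trial_energy(solve_prepared(ctx_exo))$total_energy_per_kg
    e_set <- numeric(n_set)
    infeasible <- integer(n_set)
    for (g in seq_len(n_set)) {
      setting <- exo_setting(grid$stiffness_k[g], grid$timing_tau[g])
      sol <- solve_prepared(ctx_exo, exo_torque_window(ctx_exo, setting))
      e_set[g] <- trial_energy(sol)$total_energy_per_kg
      infeasible[g] <- sum(!sol$feasible)
    }
    records[[t]] <- data.frame(
      contact = t, side = trial$side,
      stiffness_k = grid$stiffness_k, timing_tau = grid$timing_tau,
      energy_per_kg = e_set,
      baseline_per_kg = baseline[t],
      delta_pct = 100 * (e_set - baseline[t]) / baseline[t],
      infeasible_steps = infeasible
    )
    if (progress) {
      message(sprintf("contact %d/%d done (%d settings)", t, n_trial, n_set))
    }
  }
  per_contact <- do.call(rbind, records)
  agg_mean <- stats::aggregate(delta_pct ~ stiffness_k + timing_tau,
                               per_contact, mean)
  agg_sd <- stats::aggregate(delta_pct ~ stiffness_k + timing_tau,
                             per_contact, stats::sd)
  agg_inf <- stats::aggregate(infeasible_steps ~ stiffness_k + timing_tau,
                              per_contact, sum)
  cell <- merge(merge(agg_mean, agg_sd,
                      by = c("stiffness_k", "timing_tau"),
                      suffixes = c("_mean", "_sd")),
                agg_inf, by = c("stiffness_k", "timing_tau"))
  names(cell) <- c("stiffness_k", "timing_tau", "delta_pct_mean",
                   "delta_pct_sd", "infeasible_steps")
  cell$n_contacts <- n_trial
  cell <- cell[order(cell$stiffness_k, cell$timing_tau), ]
  rownames(cell) <- NULL
  structure(
    list(
      grid = cell,
      per_contact = per_contact,
      baseline_per_contact = baseline,
      no_actuation_per_contact = no_act,
      n_simulations = n_trial * n_set,
      subject_mass = cohort[[1L]]$subject_mass
    ),
    class = "sweep_result"
  )
}

#' Locate the global and local minima of the sweep grid
#'
#' The global minimum is the cell with the smallest mean percent energy
#' change, ties broken toward lower stiffness then earlier timing.  Local
#' minima are cells strictly below all their 4-neighbors on the
#' (stiffness, timing) lattice.
#'
#' @param result A `sweep_result`.
#' @return A list with `global_minimum` (one-row data frame) and
#'   `local_minima` (data frame, possibly empty).
#' @export
find_minima <- function(result) {
  g <- result$grid
  ks <- sort(unique(g$stiffness_k))
  taus <- sort(unique(g$timing_tau))
  z <- matrix(NA_real_, length(ks), length(taus))
  z[cbind(match(g$stiffness_k, ks), match(g$timing_tau, taus))] <-
    g$delta_pct_mean
  # global minimum with deterministic tie-break (lower k, then earlier tau)
  ord <- order(g$delta_pct_mean, g$stiffness_k, g$timing_tau)
  global <- g[ord[1L], c("stiffness_k", "timing_tau", "delta_pct_mean")]
  rownames(global) <- NULL
  # strict 4-neighbor local minima
  locs <- list()
  for (i in seq_along(ks)) {
    for (j in seq_along(taus)) {
      v <- z[i, j]
      if (is.na(v)) next
      nb <- c(
        if (i > 1) z[i - 1, j], if (i < length(ks)) z[i + 1, j],
        if (j > 1) z[i, j - 1], if (j < length(taus)) z[i, j + 1]
      )
      nb <- nb[!is.na(nb)]
      if (length(nb) > 0 && all(v < nb)) {
        locs[[length(locs) + 1L]] <- data.frame(
          stiffness_k = ks[i], timing_tau = taus[j], delta_pct_mean = v
        )
      }
    }
  }
  local_minima <- if (length(locs)) do.call(rbind, locs) else
    data.frame(stiffness_k = numeric(0), timing_tau = numeric(0),
               delta_pct_mean = numeric(0))
  list(global_minimum = global, local_minima = local_minima)
}

#' Quadratic fit of mean energy change versus stiffness at one timing
#'
#' Ordinary least squares of the mean percent energy change on
#' `(1, k, k^2)` over one actuation-timing slice of the grid.
#'
#' @param result A `sweep_result`.
#' @param tau Actuation timing [\% of stance]; must be a grid timing.
#' @return A list with coefficients `c0`, `c1`, `c2`, the vertex stiffness
#'   `vertex_k = -c1 / (2 c2)` (`NA` with `has_interior_minimum = FALSE`
#'   when `c2 <= 0`), and `r_squared`.
#' @export
quadratic_fit <- function(result, tau = 15) {
  g <- result$grid[result$grid$timing_tau == tau, ]
  if (nrow(g) < 3L) {
    stop_invalid("need at least 3 stiffness points at tau = %g", tau)
  }
  k <- g$stiffness_k
  y <- g$delta_pct_mean
  fit <- stats::lm(y ~ k + I(k^2))
  cf <- unname(stats::coef(fit))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  has_min <- is.finite(cf[3L]) && cf[3L] > 0
  list(
    c0 = cf[1L], c1 = cf[2L], c2 = cf[3L],
    vertex_k = if (has_min) -cf[2L] / (2 * cf[3L]) else NA_real_,
    has_interior_minimum = has_min,
    r_squared = 1 - ss_res / ss_tot,
    tau = tau, n = nrow(g)
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  mins <- find_minima(x)
  cat(sprintf(
    "<sweep_result> %d settings x %d contacts = %d simulations\n",
    nrow(x$grid), length(x$baseline_per_contact), x$n_simulations
  ))
  cat(sprintf(
    "  baseline %.3f +/- %.3f J/kg; no actuation %.3f +/- %.3f J/kg\n",
    mean(x$baseline_per_contact), stats::sd(x$baseline_per_contact),
    mean(x$no_actuation_per_contact), stats::sd(x$no_actuation_per_contact)
  ))
  gm <- mins$global_minimum
  cat(sprintf(
    "  global minimum: %+.2f%% at k = %.0f N/m, tau = %.0f%% of stance\n",
    gm$delta_pct_mean, gm$stiffness_k, gm$timing_tau
  ))
  invisible(x)
}
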