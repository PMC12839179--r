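test_that("spring length reproduces elementary triangles", {
  g_collinear <- exo_geometry(shank_attach_r = 0.1, foot_attach_r = 0.1,
                              attach_offset_angle = pi)
  expect_equal(spring_length(0, g_collinear), 0.2)
  g_right <- exo_geometry(shank_attach_r = 0.3, foot_attach_r = 0.4,
                          attach_offset_angle = pi / 2)
  expect_equal(spring_length(0, g_right), 0.5)
})

test_that("spring length and torque match the 2-D coordinate oracle", {
  set.seed(42)
  for (i in 1:1000) {
    r1 <- runif(1, 0.05, 0.5)
    r2 <- runif(1, 0.05, 0.5)
    off <- runif(1, 0.3, pi - 0.3)
    th <- runif(1, -0.6, 0.6)
    phi1 <- runif(1, 0, 2 * pi)  # arbitrary frame orientation
    g <- exo_geometry(shank_attach_r = r1, foot_attach_r = r2,
                      attach_offset_angle = off)
    p1 <- r1 * c(cos(phi1), sin(phi1))
    p2 <- r2 * c(cos(phi1 + off + th), sin(phi1 + off + th))
    expect_equal(spring_length(th, g), sqrt(sum((p1 - p2)^2)),
                 tolerance = 1e-9)
    # tension F pulls the foot attachment toward the shank attachment;
    # plantarflexion-positive torque is minus the z-torque in the
    # dorsiflexion-positive frame
    f <- runif(1, 0, 500)
    u <- (p1 - p2) / sqrt(sum((p1 - p2)^2))
    tz <- p2[1L] * f * u[2L] - p2[2L] * f * u[1L]
    expect_equal(spring_ankle_torque(th, f, g), -tz, tolerance = 1e-9)
  }
})

test_that("zero force gives zero torque and a known moment arm scales it", {
  g <- exo_geometry()
  expect_equal(spring_ankle_torque(0.1, 0, g), 0)
  arm <- spring_moment_arm(0.1, g)
  expect_equal(spring_ankle_torque(0.1, 100, g), 100 * arm)
  expect_equal(spring_ankle_torque(0.1, 100, g) /
                 spring_ankle_torque(0.1, 50, g), 2)
})

test_that("resting length realizes the requested actuation timing", {
  trial <- monotone_trial()
  g <- exo_geometry()
  win_first <- simulation_window(trial)[1L]
  expect_equal(resting_length_for_timing(trial, g, 15),
               spring_length(trial$ankle_angle[win_first], g))
  i60 <- which(trial$stance_fraction >= 0.60)[1L]
  expect_equal(resting_length_for_timing(trial, g, 60),
               spring_length(trial$ankle_angle[i60], g))
  expect_error(resting_length_for_timing(trial, g, 10), "15")
  expect_error(resting_length_for_timing(trial, g, 65), "15")
})

test_that("on monotone trials L0 matches the exhaustive first-crossing scan", {
  trial <- monotone_trial()
  g <- exo_geometry()
  len <- spring_length(trial$ankle_angle, g)
  prev <- -Inf
  for (tau in seq(15, 60, 5)) {
    L0 <- resting_length_for_timing(trial, g, tau)
    # brute-force scan: first sample whose length strictly exceeds L0
    first_engaged <- which(len > L0)[1L]
    first_at_tau <- which(trial$stance_fraction >= tau / 100)[1L]
    expect_gte(first_engaged, first_at_tau)
    # longer resting lengths at later timings
    expect_gte(L0, prev)
    prev <- L0
  }
})

test_that("the tension-only force law holds exactly", {
  expect_equal(spring_force(0.30, 0.35, 5500), 0)  # slack
  expect_equal(spring_force(0.35, 0.35, 5500), 0)  # tie at L0
  expect_equal(spring_force(0.37, 0.35, 5500), 110)
  expect_equal(spring_force(0.37, 0.35, 17500), 350)
  expect_error(spring_force(0.3, 0.35, -1), "positive")
  expect_error(spring_force(0.3, 0, 5500), "positive")
})

test_that("elastic energy is quadratic, slack-safe and path-independent", {
  expect_equal(spring_energy(0.30, 0.35, 5500), 0)
  expect_equal(spring_energy(0.37, 0.35, 5500), 1.1)
  # a closed loading/unloading path returns to its initial stored energy
  path <- 0.35 + 0.03 * sin(seq(0, 2 * pi, length.out = 57))
  e <- spring_energy(path, 0.34, 8000)
  expect_equal(e[1L], e[length(e)])
})

test_that("elastic bookkeeping closes over a noise-free trial", {
  trial <- quiet_trial()
  g <- exo_geometry()
  L0 <- resting_length_for_timing(trial, g, 15)
  win <- simulation_window(trial)
  len <- spring_length(trial$ankle_angle[win], g)
  k <- 8000
  stored <- spring_energy(len, L0, k)
  i_peak <- which.max(stored)
  # work returned between peak stretch and the final sample, integrating
  # the piecewise-linear force exactly (splitting segments at the L0 kink)
  released <- 0
  for (i in i_peak:(length(len) - 1L)) {
    l1 <- len[i]; l2 <- len[i + 1L]
    seg <- sort(c(l1, l2, min(max(L0, min(l1, l2)), max(l1, l2))))
    for (j in 1:2) {
      f1 <- spring_force(seg[j], L0, k)
      f2 <- spring_force(seg[j + 1L], L0, k)
      released <- released + (f1 + f2) / 2 * (seg[j + 1L] - seg[j]) *
        sign(l2 - l1)
    }
  }
  expect_lt(abs((stored[i_peak] - stored[length(len)]) + released), 1e-9)
})

test_that("added-mass adjustments follow the point-mass gravitational model", {
  trial <- quiet_trial()
  g0 <- exo_geometry(bracket_mass_foot = 0, bracket_mass_shank = 0)
  adj0 <- added_mass_moments(trial, g0)
  expect_true(all(adj0 == 0))

  # horizontal foot segment: magnitude m * g * lever
  n <- 80L
  s <- seq(0, 1.12, length.out = n)
  flat <- gait_trial(
    time = s * 0.65, stance_fraction = s,
    ankle_angle = ifelse(s <= 1, 0, -(s - 1)),
    knee_angle = numeric(n), hip_angle = numeric(n),
    ankle_moment = numeric(n), knee_moment = numeric(n),
    hip_moment = numeric(n),
    side = "left", subject_mass = 87.6, subject_height = 1.86
  )
  g1 <- exo_geometry(bracket_mass_foot = 0.3, bracket_mass_shank = 0,
                     mass_lever_foot = 0.1)
  expect_equal(added_mass_moments(flat, g1)$ankle[1L], 0.3 * 9.81 * 0.1)

  # point-mass oracle: horizontal offsets of explicit mass positions
  g2 <- exo_geometry(bracket_mass_foot = 0.7, bracket_mass_shank = 0.4,
                     mass_lever_foot = 0.14, mass_lever_shank = 0.06)
  adj <- added_mass_moments(trial, g2)
  foot_x <- 0.14 * cos(trial$ankle_angle)
  shank_x <- 0.14 * cos(trial$knee_angle)
  lever_knee_x <- 0.06 * cos(trial$knee_angle)
  expect_equal(adj$ankle, 9.81 * (0.7 * foot_x + 0.4 * shank_x),
               tolerance = 1e-12)
  expect_equal(adj$knee, 9.81 * 0.4 * lever_knee_x, tolerance = 1e-12)
  expect_equal(adj$hip, numeric(length(trial$time)))
})

test_that("spring force and torque vanish before the actuation timing", {
  trial <- quiet_trial()
  g <- exo_geometry()
  mus <- default_muscle_set()
  ctx <- exosweep:::prepare_trial_context(trial, mus, g)
  sf <- trial$stance_fraction[ctx$window]
  for (tau in seq(15, 60, 5)) {
    tq <- exosweep:::exo_torque_window(ctx, exo_setting(8000, tau))
    expect_true(all(tq[sf < tau / 100] == 0))
    expect_true(all(tq >= 0))
  }
})
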