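test_that("the default muscle set is complete, valid and mass-scaled", {
  mus <- default_muscle_set(subject_mass = 87.6, subject_height = 1.86)
  expect_equal(nrow(mus), 16L)
  expect_equal(as.integer(table(mus$side)[c("left", "right")]), c(8L, 8L))
  expect_true(all(mus$f_max > 0))
  expect_true(all(mus$l_opt > 0))
  expect_true(all(mus$v_max > 0))
  expect_true(all(mus$muscle_mass > 0))
  expect_true(all(mus$fast_twitch_fraction >= 0 &
                    mus$fast_twitch_fraction <= 1))
  # linear mass scaling against the shipped base table
  base <- utils::read.csv(
    system.file("extdata", "muscle_params.csv", package = "exosweep"),
    comment.char = "#"
  )
  left <- mus[mus$side == "left", ]
  expect_equal(left$f_max, base$f_max * 87.6 / 75.2, tolerance = 1e-12)
  expect_equal(left$l_opt, base$l_opt * 1.86 / 1.70, tolerance = 1e-12)
})

test_that("ankle moment-arm signs follow the plantarflexion convention", {
  mus <- default_muscle_set()
  left <- mus[mus$side == "left", ]
  arms <- moment_arm_matrix(left, list(ankle = 0, knee = 0, hip = 0))
  pf <- c("soleus", "gastroc_med", "gastroc_lat")
  expect_true(all(arms$ankle[1L, pf] > 0))
  expect_lt(arms$ankle[1L, "tib_ant"], 0)
  expect_gt(arms$knee[1L, "vasti"], 0)        # knee extensor
  expect_lt(arms$knee[1L, "hamstrings"], 0)   # knee flexor
  expect_gt(arms$hip[1L, "glut_max"], 0)      # hip extensor
  expect_equal(unname(arms$knee[1L, "soleus"]), 0)    # does not span the knee
})

test_that("rigid-tendon fiber kinematics follow the moment-arm integral", {
  # constant joint angles: zero fiber velocity everywhere
  n <- 60L
  still <- list(time = seq(0, 1, length.out = n),
                ankle_angle = rep(0.2, n), knee_angle = rep(0.3, n),
                hip_angle = rep(-0.1, n))
  mus <- toy_muscles(2L)
  kin <- muscle_kinematics(still, mus)
  expect_true(all(kin$norm_vel == 0))

  # constant moment arm r: fiber length change = r * dtheta / cos(pennation)
  ramp <- list(time = seq(0, 1, length.out = n),
               ankle_angle = seq(0, 0.4, length.out = n),
               knee_angle = numeric(n), hip_angle = numeric(n))
  kin2 <- muscle_kinematics(ramp, mus)
  dl <- (kin2$norm_len[n, 1L] - kin2$norm_len[1L, 1L]) * mus$l_opt[1L]
  expect_equal(unname(dl), mus$ankle_r0[1L] * 0.4, tolerance = 1e-12)

  # angle-dependent arm: matches fine-grid quadrature of the arm polynomial
  mus_var <- toy_muscles(1L)
  mus_var$ankle_r1 <- -0.02
  kin3 <- muscle_kinematics(ramp, mus_var)
  th <- ramp$ankle_angle
  quad <- vapply(th, function(t) {
    stats::integrate(function(u) mus_var$ankle_r0 + mus_var$ankle_r1 * u,
                     0, t, rel.tol = 1e-12)$value
  }, numeric(1L))
  lf <- mus_var$l_opt + quad / cos(mus_var$pennation)
  expect_equal(kin3$norm_len[, 1L], lf / mus_var$l_opt, tolerance = 1e-9)
})

test_that("degenerate fiber geometry names the offending muscle", {
  mus <- toy_muscles(1L)
  mus$ankle_r0 <- 0.5  # absurd arm drives fiber length negative
  ramp <- list(time = seq(0, 1, length.out = 50),
               ankle_angle = seq(0, -0.5, length.out = 50),
               knee_angle = numeric(50), hip_angle = numeric(50))
  expect_error(muscle_kinematics(ramp, mus), "m1")
})

test_that("the Hill curves honor their endpoint contracts", {
  expect_equal(force_length(1), 1)
  lgrid <- seq(0.4, 1.8, by = 0.01)
  expect_true(all(force_length(lgrid) <= 1))
  expect_equal(force_velocity(0), 1)
  expect_equal(force_velocity(1), 0)
  vgrid <- seq(-1, 1, by = 0.01)
  expect_true(all(diff(force_velocity(vgrid)) <= 1e-12))  # non-increasing
  expect_true(all(force_velocity(vgrid) <= 1.5))
  expect_equal(force_passive(1), 0)
  expect_equal(force_passive(0.8), 0)

  p <- toy_muscles(1L)
  iso <- list(activation = 1, norm_fiber_length = 1, norm_fiber_velocity = 0)
  expect_equal(muscle_force(iso, p[1L, ], include_passive = FALSE),
               p$f_max[1L])
  off <- list(activation = 0, norm_fiber_length = 1.1,
              norm_fiber_velocity = 0.3)
  expect_equal(muscle_force(off, p[1L, ], include_passive = FALSE), 0)
  vmax <- list(activation = 1, norm_fiber_length = 1,
               norm_fiber_velocity = 1)
  expect_equal(muscle_force(vmax, p[1L, ], include_passive = FALSE), 0)
})

test_that("muscle force is non-decreasing in activation at fixed state", {
  p <- toy_muscles(1L)[1L, ]
  set.seed(7)
  for (i in 1:50) {
    st <- list(norm_fiber_length = runif(1, 0.6, 1.4),
               norm_fiber_velocity = runif(1, -0.8, 0.9))
    acts <- seq(0, 1, by = 0.1)
    f <- vapply(acts, function(a) {
      muscle_force(c(st, activation = a), p)
    }, numeric(1L))
    expect_true(all(diff(f) >= -1e-12))
  }
})

test_that("moment arm equals the musculotendon length derivative", {
  # r(theta) must equal dL/dtheta (moment-positive convention) to 1e-6
  mus <- toy_muscles(1L)
  mus$ankle_r1 <- -0.015
  h <- 1e-6
  mt_len <- function(theta) {
    kin <- muscle_kinematics(
      list(time = c(0, 1), ankle_angle = rep(theta, 2),
           knee_angle = c(0, 0), hip_angle = c(0, 0)),
      mus
    )
    kin$norm_len[1L, 1L] * mus$l_opt * cos(mus$pennation)
  }
  for (theta in seq(-0.3, 0.3, by = 0.1)) {
    num <- (mt_len(theta + h) - mt_len(theta - h)) / (2 * h)
    r <- mus$ankle_r0 + mus$ankle_r1 * theta
    expect_equal(unname(num), r, tolerance = 1e-6)
  }
})
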