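test_that("required moments combine net, exoskeleton and mass terms", {
  trial <- monotone_trial(ankle_moment = rep(80, 80))
  req0 <- required_moments(trial)
  expect_equal(req0$ankle, trial$ankle_moment)
  expect_equal(req0$knee, trial$knee_moment)
  req <- required_moments(trial, exo_torque = rep(20, 80))
  expect_equal(req$ankle, rep(60, 80))
  # exoskeleton torque above the net moment passes through as negative
  req_neg <- required_moments(trial, exo_torque = rep(100, 80))
  expect_equal(req_neg$ankle, rep(-20, 80))
})

test_that("zero demand with no passive force gives the zero solution", {
  mus <- toy_muscles(2L)
  sol <- solve_static_optimization(
    c(ankle = 0, knee = 0, hip = 0),
    isometric_states(2L), mus, list(ankle = 0, knee = 0, hip = 0)
  )
  expect_equal(unname(sol$activations), c(0, 0))
  expect_equal(sol$objective, 0)
  expect_true(sol$feasible)
})

test_that("static optimization matches dense grid search on 2-muscle instances", {
  # weak muscles + unit reserve weight keep the objective resolvable on the
  # 1e-3 lattice (see helper); the solver path is weight-independent
  mus <- toy_muscles(2L, f_max = c(30, 24))
  set.seed(11)
  for (i in 1:100) {
    required <- runif(1, 0, 2.5)
    states <- list(norm_fiber_length = runif(2, 0.8, 1.2),
                   norm_fiber_velocity = runif(2, -0.3, 0.3))
    sol <- solve_static_optimization(
      c(ankle = required, knee = 0, hip = 0), states, mus,
      list(ankle = 0, knee = 0, hip = 0), reserve_weight = 1
    )
    gains <- mus$f_max * force_length(states$norm_fiber_length) *
      force_velocity(states$norm_fiber_velocity)
    passive <- mus$f_max * force_passive(states$norm_fiber_length)
    b <- required - sum(passive * mus$ankle_r0)
    ref <- grid_search_2muscle(b, gains, mus$ankle_r0)
    expect_lt(max(abs(unname(sol$activations) - ref)), 2e-3)
  }
})

test_that("demand beyond muscle capacity flows into reserves and is flagged", {
  mus <- toy_muscles(2L)
  capacity <- sum(mus$f_max * mus$ankle_r0) * 1.5  # generous upper bound
  sol <- solve_static_optimization(
    c(ankle = capacity + 100, knee = 0, hip = 0),
    isometric_states(2L), mus, list(ankle = 0, knee = 0, hip = 0)
  )
  expect_false(sol$feasible)
  expect_gt(abs(sol$reserves[["ankle"]]), 1)
  expect_equal(unname(sol$activations), c(1, 1))
})

test_that("the solver beats random feasible points on 3-muscle instances", {
  mus <- toy_muscles(3L)
  w <- 1e3
  set.seed(13)
  for (i in 1:20) {
    required <- runif(1, -40, 150)
    states <- list(norm_fiber_length = runif(3, 0.8, 1.2),
                   norm_fiber_velocity = runif(3, -0.3, 0.3))
    sol <- solve_static_optimization(
      c(ankle = required, knee = 0, hip = 0), states, mus,
      list(ankle = 0, knee = 0, hip = 0), reserve_weight = w
    )
    gains <- mus$f_max * force_length(states$norm_fiber_length) *
      force_velocity(states$norm_fiber_velocity)
    passive <- mus$f_max * force_passive(states$norm_fiber_length)
    b <- required - sum(passive * mus$ankle_r0)
    full_obj <- function(a) {
      sum(a^2) + w * (b - sum(a * gains * mus$ankle_r0))^2
    }
    best <- full_obj(unname(sol$activations))
    rand <- matrix(runif(3 * 50), ncol = 3)
    expect_true(all(apply(rand, 1L, full_obj) >= best - 1e-9))
  }
})

test_that("KKT residuals vanish at reported optima", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    A <- matrix(rnorm(n * n), n)
    H <- crossprod(A) + diag(2, n)
    f <- rnorm(n, sd = 5)
    a <- exosweep:::solve_box_qp(H, f)
    g <- drop(H %*% a) - f
    free <- a > 1e-9 & a < 1 - 1e-9
    expect_true(all(abs(g[free]) < 1e-6))
    expect_true(all(g[a <= 1e-9] > -1e-6))
    expect_true(all(g[a >= 1 - 1e-9] < 1e-6))
  }
})

test_that("solve_trial is deterministic and windowed at 15% of stance", {
  trial <- quiet_trial()
  mus <- default_muscle_set()
  sol1 <- solve_trial(trial, mus)
  sol2 <- solve_trial(trial, mus)
  expect_identical(sol1, sol2)
  expect_equal(sol1$window[1L], which(trial$stance_fraction >= 0.15)[1L])
  expect_equal(sol1$window[length(sol1$window)],
               trial$events[["max_plantarflexion"]])
  expect_true(all(sol1$activations >= 0 & sol1$activations <= 1))
  # ipsilateral muscles only
  expect_true(all(sol1$muscles$side == trial$side))
})

test_that("a vanishing spring stiffness recovers the no-exoskeleton solution", {
  trial <- quiet_trial()
  mus <- default_muscle_set()
  g <- exo_geometry(bracket_mass_foot = 0, bracket_mass_shank = 0)
  base <- solve_trial(trial, mus)
  tiny <- solve_trial(trial, mus, geometry = g,
                      setting = exo_setting(1e-6, 15))
  expect_lt(max(abs(base$activations - tiny$activations)), 1e-6)
})

test_that("plantarflexion assistance never raises the per-step objective", {
  mus <- toy_muscles(2L)  # two plantarflexors
  set.seed(19)
  for (i in 1:30) {
    net <- runif(1, 20, 150)
    assist <- runif(1, 0, net)  # requirement stays non-negative
    states <- list(norm_fiber_length = runif(2, 0.9, 1.1),
                   norm_fiber_velocity = runif(2, -0.2, 0.2))
    sol0 <- solve_static_optimization(
      c(ankle = net, knee = 0, hip = 0), states, mus,
      list(ankle = 0, knee = 0, hip = 0)
    )
    sol1 <- solve_static_optimization(
      c(ankle = net - assist, knee = 0, hip = 0), states, mus,
      list(ankle = 0, knee = 0, hip = 0)
    )
    expect_lte(sol1$objective, sol0$objective + 1e-12)
  }
})

test_that("an empty muscle set is rejected", {
  mus <- toy_muscles(2L)[0L, ]
  expect_error(
    solve_static_optimization(c(ankle = 1, knee = 0, hip = 0),
                              isometric_states(0L), mus,
                              list(ankle = 0, knee = 0, hip = 0)),
    "empty"
  )
})
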