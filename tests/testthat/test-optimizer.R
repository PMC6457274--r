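test_that("excitation splines interpolate, stay periodic and clip", {
  period <- 1.2
  t <- seq(0, period, length.out = 101L)
  expect_equal(excitation_signal(rep(0.3, 10L), t, period), rep(0.3, 101L))

  nodes <- c(0.4, 0.5, 0.45, 0.6, 0.5, 0.4, 0.35, 0.5, 0.55, 0.45)
  tn <- seq(0, period, length.out = 11L)[1:10]
  expect_equal(excitation_signal(nodes, tn, period), nodes, tolerance = 1e-10)
  u <- excitation_spline(nodes, period)
  expect_equal(u(0), u(period), tolerance = 1e-12)
  # overshoot from extreme nodes is clipped into [0, 1]
  spiky <- excitation_spline(c(0, 1, 0, 1, 0), period)
  vals <- spiky(seq(0, period, length.out = 400L))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_error(excitation_spline(c(0.5, 1.2), period), "\\[0, 1\\]")
})

test_that("the full control vector has 154 variables and round-trips", {
  shp <- printed_shape()
  exc <- matrix(0.5, 15L, 10L, dimnames = list(default_muscles()$name, NULL))
  x <- assemble_controls(exc, shp)
  expect_length(x, 154L)
  expect_length(assemble_controls(matrix(0.5, 1L, 10L), shp), 14L)

  set.seed(5)
  exc2 <- matrix(runif(150), 15L, 10L)
  x2 <- assemble_controls(exc2, shp)
  d <- disassemble_controls(x2)
  expect_equal(d$excitations, exc2)
  expect_equal(d$shape$A, shp$A)
  expect_equal(d$shape$beta, shp$beta)
  expect_error(disassemble_controls(x2[-1L], 15L, 10L), "length")
})

test_that("control bounds cover excitations, scales, exponent and tilt", {
  b <- control_bounds(15L, 10L)
  expect_length(b$lower, 154L)
  expect_equal(b$lower[151:154], c(0.030, 0.030, 0, -pi / 2))
  expect_equal(b$upper[151:154], c(0.155, 0.155, 1, pi / 2))
})

small_setup <- function(muscles = four_muscle_set(), n_nodes = 5L)
  propulsion_setup(muscles = muscles, n_nodes = n_nodes,
                   n_out = 120L, n_path = 360L)

test_that("the objective rewards power, penalizes infeasibility, and is deterministic", {
  setup <- small_setup()
  zero <- assemble_controls(matrix(0, 4L, 5L), path_shape(0.1, 0.1, 0))
  rep0 <- propulsion_objective(zero, setup)
  # no muscle activity cannot yield positive net power (continuous limit;
  # allow the quadrature residual of the cycle average)
  expect_gte(rep0$total, -1e-2)
  expect_lte(rep0$net_power, 1e-2)
  expect_true(rep0$feasible)

  # identical controls evaluate to the identical objective
  set.seed(9)
  x <- assemble_controls(matrix(runif(20L), 4L, 5L), printed_shape())
  r1 <- propulsion_objective(x, setup)
  r2 <- propulsion_objective(x, setup)
  expect_identical(r1, r2)

  # an unreachable path is strictly worse than any feasible one
  short_arm <- arm_config(l_upper = 0.2, l_fore = 0.2)
  setup_short <- propulsion_setup(muscles = four_muscle_set(), n_nodes = 5L,
                                  arm = short_arm, n_out = 120L, n_path = 360L)
  rep_un <- propulsion_objective(x, setup_short)
  expect_false(rep_un$feasible)
  expect_gte(rep_un$total, setup$weights$shape)
  expect_gt(rep_un$total, r1$total)
})

test_that("crank-length excursions below the slider travel are penalized", {
  setup <- small_setup()
  pinch <- assemble_controls(matrix(0, 4L, 5L), path_shape(0.155, 0.030, 1))
  rep_p <- propulsion_objective(pinch, setup)
  expect_gt(rep_p$penalties$cl_bounds, 0)
  expect_false(rep_p$feasible)
})

# cheap synthetic objective: concave in the shape block, maximized by an
# untilted circle; exercises the full search loop without simulation
circle_objective <- function(x, setup) {
  d <- disassemble_controls(x, nrow(setup$muscles), setup$n_nodes)
  list(total = d$shape$n^2 + ((d$shape$A - d$shape$B) / 0.02)^2,
       net_power = NA_real_)
}

test_that("accepted-iterate history is monotone and seed-reproducible", {
  setup <- small_setup(pair_muscle_set())
  f1 <- suppressWarnings(optimize_propulsion(setup, seed = 42L, n_iter = 150L,
                                             objective = circle_objective))
  expect_true(all(diff(f1$history$total) <= 0))
  f2 <- suppressWarnings(optimize_propulsion(setup, seed = 42L, n_iter = 150L,
                                             objective = circle_objective))
  expect_identical(f1$par, f2$par)
  expect_identical(f1$history, f2$history)
  f3 <- suppressWarnings(optimize_propulsion(setup, seed = 43L, n_iter = 150L,
                                             objective = circle_objective))
  expect_false(identical(f3$par, f1$par))
})

test_that("the search recovers the circle on the circle-favoring objective", {
  setup <- small_setup(pair_muscle_set())
  fit <- suppressWarnings(optimize_propulsion(setup, seed = 1L, n_iter = 200L,
                                              objective = circle_objective))
  d <- disassemble_controls(fit$par, 2L, 5L)
  expect_lte(d$shape$n, 0.2)
  expect_lte(abs(d$shape$A - d$shape$B), 0.02)
})

test_that("optimization improves on its own random start", {
  setup <- small_setup()
  fit <- suppressWarnings(optimize_propulsion(setup, seed = 2L, n_iter = 15L))
  expect_lte(fit$report$total, fit$initial_report$total)
  expect_true(all(fit$par >= control_bounds(4L, 5L)$lower - 1e-12))
  expect_true(all(fit$par <= control_bounds(4L, 5L)$upper + 1e-12))
})
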