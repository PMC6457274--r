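test_that("inverse kinematics solves the canonical configurations", {
  arm <- arm_config()
  reach <- arm$l_upper + arm$l_fore
  # full extension along an arbitrary direction
  p <- arm$shoulder + reach * c(cos(-0.7), sin(-0.7))
  expect_equal(inverse_kinematics(p, arm)$flexion_deg, 0, tolerance = 1e-5)
  # Pythagorean configuration gives 90 degrees of flexion
  d90 <- sqrt(arm$l_upper^2 + arm$l_fore^2)
  p90 <- arm$shoulder + d90 * c(cos(-1.1), sin(-1.1))
  expect_equal(inverse_kinematics(p90, arm)$flexion_deg, 90, tolerance = 1e-9)
  expect_error(inverse_kinematics(arm$shoulder + c(1.0, 0), arm),
               "unreachable")
})

test_that("forward kinematics inverts inverse kinematics to 1e-10 m", {
  arm <- arm_config()
  set.seed(101)
  n <- 100L
  d <- runif(n, abs(arm$l_upper - arm$l_fore) + 0.01,
             arm$l_upper + arm$l_fore - 0.01)
  ang <- runif(n, -pi, pi)
  pts <- cbind(arm$shoulder[1L] + d * cos(ang), arm$shoulder[2L] + d * sin(ang))
  for (b in c("up", "down")) {
    ik <- inverse_kinematics(pts, arm, branch = b)
    back <- forward_kinematics(arm, ik$q[, 1L], ik$q[, 2L])
    expect_lt(max(abs(back - pts)), 1e-10)
  }
})

test_that("prescribed-path kinematics is periodic and its velocities are consistent", {
  prof <- printed_profile()
  arm <- arm_config()
  mech <- mechanism_config()
  period <- 2 * pi / mech$omega
  t <- seq(0, period, length.out = 241L)
  pose <- path_kinematics(prof, arm, mech, t)
  expect_equal(pose$q[1L, ], pose$q[241L, ], tolerance = 1e-9)

  # central-difference oracle against the Jacobian velocities, on a smooth
  # (circular) profile
  circ <- to_crank_length_profile(sample_path(path_shape(0.12, 0.12, 0), 720L))
  h <- 1e-5 * period
  for (tc in c(0.31, 0.77) * period) {
    p3 <- path_kinematics(circ, arm, mech, c(tc - h, tc, tc + h), branch = "up")
    fd <- (p3$q[3L, ] - p3$q[1L, ]) / (2 * h)
    expect_lt(max(abs(fd - p3$qd[2L, ])), 1e-6)
  }
})

test_that("a circular path about the shoulder keeps elbow flexion constant", {
  mech <- mechanism_config(center = c(0.25, -0.44))
  arm <- arm_config(shoulder = mech$center)  # concentric by construction
  prof <- to_crank_length_profile(sample_path(path_shape(0.15, 0.15, 0), 720L))
  t <- seq(0, 2 * pi / mech$omega, length.out = 97L)
  pose <- path_kinematics(prof, arm, mech, t, branch = "up")
  expect_lt(diff(range(pose$flexion_deg)), 1e-6)
})

test_that("joint-limit torques engage only beyond the range and oppose excursion", {
  arm <- arm_config(k_limit = 20, c_limit = 1,
                    shoulder_range_deg = c(-90, 30), elbow_range_deg = c(0, 130))
  mid <- matrix(c(-0.5, 0.8), 1L)
  expect_equal(joint_limit_torque(mid, matrix(0, 1, 2), arm),
               matrix(0, 1, 2))
  # 0.1 rad beyond the shoulder upper limit, at rest: -K * excursion
  over <- matrix(c(30 * pi / 180 + 0.1, 0.8), 1L)
  tau <- joint_limit_torque(over, matrix(0, 1, 2), arm)
  expect_equal(tau[1L, 1L], -2.0, tolerance = 1e-12)
  expect_equal(tau[1L, 2L], 0)
  # torque sign always opposes the excursion direction
  under <- matrix(c(-120 * pi / 180, -0.2), 1L)
  tau2 <- joint_limit_torque(under, matrix(0, 1, 2), arm)
  expect_gt(tau2[1L, 1L], 0)
  expect_gt(tau2[1L, 2L], 0)
})

test_that("inverse dynamics reduces to gravity moments at a static pose", {
  arm <- arm_config()
  q <- matrix(c(-1.2, 0.9), 1L)
  static <- list(q = q, qd = matrix(0, 1, 2), qdd = matrix(0, 1, 2))
  g_off <- arm_config(gravity = c(0, 0))
  expect_equal(inverse_dynamics(static, g_off), matrix(0, 1, 2))

  tau <- inverse_dynamics(static, arm)
  g <- 9.81
  # hand-computed gravity moments on the fixture anthropometry
  t2 <- arm$m_fore * arm$com_fore * g * cos(q[1L] + q[2L])
  t1 <- (arm$m_upper * arm$com_upper + arm$m_fore * arm$l_upper) * g *
    cos(q[1L]) + t2
  expect_equal(tau, cbind(t1, t2), ignore_attr = TRUE, tolerance = 1e-12)

  heavy <- arm_config(m_upper = 4.0, m_fore = 3.4)
  expect_equal(inverse_dynamics(static, heavy), 2 * tau, tolerance = 1e-12)
})

test_that("passive simulation produces near-zero activations and no net power", {
  prof <- printed_profile()
  mus <- four_muscle_set()
  arm <- arm_config()
  mech <- mechanism_config()
  tr <- simulate_cycles(prof, matrix(0, 4L, 10L), mus, arm, mech,
                        a0 = 0, n_out = 480L)
  expect_lt(max(tr$a), 1e-8)
  # the continuous net power is non-positive; allow the quadrature residual
  expect_lt(net_propulsion_power(tr), 1e-2)
})

test_that("constant excitation settles every activation to its value", {
  prof <- printed_profile()
  mus <- four_muscle_set()
  tr <- simulate_cycles(prof, matrix(0.05, 4L, 10L), mus, arm_config(),
                        mechanism_config(), n_out = 120L)
  expect_equal(max(abs(tr$a[nrow(tr$a), ] - 0.05)), 0, tolerance = 1e-6)
})

test_that("crank work balances musculotendon plus passive work", {
  prof <- printed_profile()
  mus <- default_muscles()
  set.seed(3)
  exc <- matrix(runif(150), 15L, 10L)
  tr <- simulate_cycles(prof, exc, mus, arm_config(), mechanism_config())
  ea <- energy_audit(tr)
  scale <- max(abs(ea$crank), abs(ea$muscle))
  # periodic state: rigid-body work vanishes, so crank = muscle + limit
  expect_lt(abs(ea$crank - (ea$muscle + ea$limit)) / scale, 0.01)
})

test_that("the evaluation cycle is cycle-to-cycle stationary", {
  prof <- printed_profile()
  set.seed(7)
  exc <- matrix(runif(150), 15L, 10L)
  tr <- simulate_cycles(prof, exc, default_muscles(), arm_config(),
                        mechanism_config(), rtol = 1e-8, atol = 1e-10)
  c3 <- trace_cycle(tr, 3L)
  c4 <- trace_cycle(tr, 4L)
  expect_lt(max(abs(c3$a - c4$a)), 1e-4)
})
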