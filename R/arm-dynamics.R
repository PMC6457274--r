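#' Planar upper-extremity configuration
#'
#' Anthropometry and passive properties of the planar (parasagittal) two-link
#' arm: upper arm and forearm+hand, with the hand rigidly welded to the
#' handle. Defaults are 50th-percentile-adult-male-style segment parameters
#' with standard centre-of-mass and radius-of-gyration fractions; they are a
#' configuration, not subject-specific measurements.
#'
#' Joint coordinates are \code{q1}, the upper-arm angle from the global +x
#' axis (mathematical sense), and \code{q2}, the forearm angle relative to
#' the upper arm; elbow flexion is \code{|q2|} and the sign of \code{q2} is
#' the elbow branch.
#'
#' @param shoulder shoulder joint position (x, y) m, global frame.
#' @param l_upper,l_fore segment lengths (m): upper arm, forearm+hand to the
#'   handle grip.
#' @param m_upper,m_fore segment masses (kg).
#' @param com_frac_upper,com_frac_fore centre-of-mass location as a fraction
#'   of segment length from the proximal joint.
#' @param rog_frac_upper,rog_frac_fore radius of gyration about the centre of
#'   mass as a fraction of segment length (sets the segment inertias).
#' @param elbow_range_deg elbow flexion range (degrees), default 0 (full
#'   extension) to 130 (flexion).
#' @param shoulder_range_deg in-plane shoulder angle range for \code{q1}
#'   (degrees).
#' @param wrist_deg fixed neutral wrist angle (degrees); the wrist carries no
#'   dynamics in the planar reduction, it only sets the handle angle.
#' @param gravity gravity vector (m/s^2).
#' @param k_limit,c_limit joint-limit elastic stiffness (N m/rad) and damping
#'   (N m s/rad), engaged only beyond a limit.
#' @return Object of class \code{"arm_config"}.
#' @export
arm_config <- function(shoulder = c(0, 0.05),
                       l_upper = 0.33, l_fore = 0.46,
                       m_upper = 2.0, m_fore = 1.7,
                       com_frac_upper = 0.436, com_frac_fore = 0.45,
                       rog_frac_upper = 0.322, rog_frac_fore = 0.368,
                       elbow_range_deg = c(0, 130),
                       shoulder_range_deg = c(-160, 10),
                       wrist_deg = 0,
                       gravity = c(0, -9.81),
                       k_limit = 20, c_limit = 1) {
  stopifnot(l_upper > 0, l_fore > 0, m_upper > 0, m_fore > 0,
            length(shoulder) == 2L, length(gravity) == 2L,
            diff(elbow_range_deg) > 0, diff(shoulder_range_deg) > 0)
  structure(list(shoulder = as.numeric(shoulder),
                 l_upper = l_upper, l_fore = l_fore,
                 m_upper = m_upper, m_fore = m_fore,
                 com_upper = com_frac_upper * l_upper,
                 com_fore = com_frac_fore * l_fore,
                 i_upper = m_upper * (rog_frac_upper * l_upper)^2,
                 i_fore = m_fore * (rog_frac_fore * l_fore)^2,
                 elbow_range = elbow_range_deg * pi / 180,
                 shoulder_range = shoulder_range_deg * pi / 180,
                 wrist = wrist_deg * pi / 180,
                 gravity = as.numeric(gravity),
                 k_limit = k_limit, c_limit = c_limit),
            class = "arm_config")
}

#' @export
print.arm_config <- function(x, ...) {
  cat(sprintf(paste0("Planar arm: shoulder (%.2f, %.2f) m; upper arm %.2f m/%.1f kg; ",
                     "forearm+hand %.2f m/%.1f kg; elbow [%.0f, %.0f] deg\n"),
              x$shoulder[1L], x$shoulder[2L], x$l_upper, x$m_upper,
              x$l_fore, x$m_fore,
              x$elbow_range[1L] * 180 / pi, x$elbow_range[2L] * 180 / pi))
  invisible(x)
}

#' Forward kinematics of the planar arm
#'
#' @param config an \code{\link{arm_config}}.
#' @param q1,q2 joint coordinates (rad), vectorized.
#' @return n-by-2 matrix of hand (handle-pin) positions (m, global frame).
#' @export
forward_kinematics <- function(config, q1, q2) {
  sweep(cbind(config$l_upper * cos(q1) + config$l_fore * cos(q1 + q2),
              config$l_upper * sin(q1) + config$l_fore * sin(q1 + q2)),
        2L, config$shoulder, "+")
}

#' Inverse kinematics of the planar arm
#'
#' Law-of-cosines two-link inverse kinematics. With the arm fully extended
#' the elbow flexion is 0; at a hand distance of
#' \code{sqrt(l_upper^2 + l_fore^2)} it is 90 degrees.
#'
#' @param handle target point (x, y) m, or an n-by-2 matrix of points.
#' @param config an \code{\link{arm_config}}.
#' @param branch \code{"up"} (q2 >= 0), \code{"down"} (q2 <= 0) or
#'   \code{"auto"}: prefer a branch whose flexion lies within the configured
#'   elbow range, the smaller-flexion branch when both do. For point sets the
#'   branch is fixed from the first point (no branch switching along a path).
#' @return List with \code{q} (n-by-2 matrix of \code{q1}, \code{q2}),
#'   \code{flexion_deg}, \code{branch} (+1/-1) and \code{in_range} (logical,
#'   flexion within the configured elbow range).
#' @export
inverse_kinematics <- function(handle, config, branch = c("auto", "up", "down")) {
  branch <- match.arg(branch)
  h <- if (is.matrix(handle)) handle else matrix(handle, ncol = 2L)
  dx <- h[, 1L] - config$shoulder[1L]
  dy <- h[, 2L] - config$shoulder[2L]
  d <- sqrt(dx^2 + dy^2)
  lo <- abs(config$l_upper - config$l_fore)
  hi <- config$l_upper + config$l_fore
  bad <- d > hi + 1e-12 | d < lo - 1e-12
  if (any(bad))
    stop(sprintf("handle point unreachable: distance %.4f m outside [%.4f, %.4f] m",
                 d[which(bad)[1L]], lo, hi))
  carg <- (d^2 - config$l_upper^2 - config$l_fore^2) /
    (2 * config$l_upper * config$l_fore)
  flex <- acos(pmin(pmax(carg, -1), 1))
  b <- switch(branch, up = 1, down = -1, auto = {
    f1 <- flex[1L]
    in_up <- f1 >= config$elbow_range[1L] - 1e-9 & f1 <= config$elbow_range[2L] + 1e-9
    # both branches share the same flexion magnitude; default to elbow-up
    if (in_up) 1 else -1
  })
  q2 <- b * flex
  q1 <- atan2(dy, dx) -
    atan2(config$l_fore * sin(q2), config$l_upper + config$l_fore * cos(q2))
  list(q = cbind(q1 = q1, q2 = q2),
       flexion_deg = flex * 180 / pi,
       branch = b,
       in_range = flex >= config$elbow_range[1L] - 1e-9 &
         flex <= config$elbow_range[2L] + 1e-9)
}

# 2x2 hand Jacobian at a single pose
.arm_jacobian <- function(config, q1, q2) {
  s1 <- sin(q1); c1 <- cos(q1)
  s12 <- sin(q1 + q2); c12 <- cos(q1 + q2)
  matrix(c(-config$l_upper * s1 - config$l_fore * s12, -config$l_fore * s12,
           config$l_upper * c1 + config$l_fore * c12, config$l_fore * c12),
         2L, 2L, byrow = TRUE)
}

#' Prescribed-path arm kinematics over a time grid
#'
#' Runs the handle over the crank-length profile at constant crank speed and
#' solves the closed chain: joint angles by inverse kinematics, joint
#' velocities through the hand Jacobian, joint accelerations by central
#' differences of the velocities (periodic when the grid spans whole cycles).
#'
#' @param profile a \code{\link{to_crank_length_profile}} object.
#' @param arm an \code{\link{arm_config}}.
#' @param mech a \code{\link{mechanism_config}}.
#' @param t strictly increasing time grid (s).
#' @param branch elbow branch, as in \code{\link{inverse_kinematics}}.
#' @return Object of class \code{"arm_pose_series"}: \code{t}, \code{theta},
#'   \code{q}, \code{qd}, \code{qdd} (n-by-2), \code{flexion_deg},
#'   \code{handle_pos}, \code{handle_vel}, \code{branch},
#'   \code{range_violation} (logical per sample) and
#'   \code{range_excursion} (rad, elbow+shoulder excursion beyond limits).
#' @export
path_kinematics <- function(profile, arm, mech, t, branch = "auto") {
  ck <- crank_kinematics(profile, mech, t)
  ik <- inverse_kinematics(ck$pos, arm, branch)
  n <- length(t)
  q <- ik$q
  qd <- matrix(0, n, 2L)
  for (i in seq_len(n))
    qd[i, ] <- solve(.arm_jacobian(arm, q[i, 1L], q[i, 2L]), ck$vel[i, ])
  periodic <- max(abs(q[1L, ] - q[n, ])) < 1e-8
  qdd <- .fd_matrix(qd, t, periodic)
  sh_exc <- pmax(0, arm$shoulder_range[1L] - q[, 1L]) +
    pmax(0, q[, 1L] - arm$shoulder_range[2L])
  flex <- abs(q[, 2L])
  el_exc <- pmax(0, arm$elbow_range[1L] - flex) +
    pmax(0, flex - arm$elbow_range[2L])
  structure(list(t = t, theta = ck$theta, q = q, qd = qd, qdd = qdd,
                 flexion_deg = ik$flexion_deg,
                 handle_pos = ck$pos, handle_vel = ck$vel,
                 branch = ik$branch,
                 range_violation = (sh_exc + el_exc) > 0,
                 range_excursion = cbind(shoulder = sh_exc, elbow = el_exc)),
            class = "arm_pose_series")
}

# column-wise time derivative: central differences, periodic wrap optional
.fd_matrix <- function(m, t, periodic) {
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  if (periodic && n > 2L) {
    # uniform-grid periodic central differences; rows 1 and n coincide
    h <- t[2L] - t[1L]
    ii <- seq_len(n - 1L)
    up <- c(seq(2L, n - 1L), 1L)
    dn <- c(n - 1L, seq_len(n - 2L))
    out[ii, ] <- (m[up, , drop = FALSE] - m[dn, , drop = FALSE]) / (2 * h)
    out[n, ] <- out[1L, ]
  } else {
    for (j in seq_len(ncol(m))) {
      out[2:(n - 1L), j] <- (m[3:n, j] - m[1:(n - 2L), j]) / (t[3:n] - t[1:(n - 2L)])
      out[1L, j] <- (m[2L, j] - m[1L, j]) / (t[2L] - t[1L])
      out[n, j] <- (m[n, j] - m[n - 1L, j]) / (t[n] - t[n - 1L])
    }
  }
  out
}

#' Passive joint-limit torques
#'
#' Elastic-plus-damping torques that enforce the joint ranges: zero inside
#' the range; beyond a limit, a linear restoring torque proportional to the
#' excursion plus a damping torque opposing the joint velocity, both engaged
#' only while outside the range.
#'
#' @param q n-by-2 matrix of joint coordinates (\code{q1}, \code{q2}), rad.
#' @param qd matching joint velocities (rad/s).
#' @param config an \code{\link{arm_config}}.
#' @param branch elbow branch sign (+1/-1) mapping the flexion range into
#'   \code{q2} space.
#' @return n-by-2 matrix of torques (N m) on (\code{q1}, \code{q2}).
#' @export
joint_limit_torque <- function(q, qd, config, branch = 1) {
  if (!is.matrix(q)) q <- matrix(q, ncol = 2L)
  if (!is.matrix(qd)) qd <- matrix(qd, ncol = 2L)
  el <- sort(branch * config$elbow_range)
  lims <- rbind(config$shoulder_range, el)
  out <- matrix(0, nrow(q), 2L)
  for (j in 1:2) {
    over <- pmax(0, q[, j] - lims[j, 2L])
    under <- pmax(0, lims[j, 1L] - q[, j])
    outside <- (over + under) > 0
    out[, j] <- -config$k_limit * over + config$k_limit * under -
      config$c_limit * qd[, j] * outside
  }
  out
}

#' Inverse dynamics of the prescribed planar motion
#'
#' Joint torques required to realize a prescribed joint trajectory of the
#' two-link arm, including inertial, Coriolis/centripetal and gravity terms
#' (standard planar two-link manipulator equations), excluding handle
#' constraint forces and muscle/limit torques.
#'
#' @param pose an \code{\link{path_kinematics}} series, or any list with
#'   \code{q}, \code{qd}, \code{qdd} matrices.
#' @param config an \code{\link{arm_config}}.
#' @return n-by-2 matrix of required torques (N m) on (\code{q1}, \code{q2}).
#' @export
inverse_dynamics <- function(pose, config) {
  q <- pose$q; qd <- pose$qd; qdd <- pose$qdd
  l1 <- config$l_upper; c1m <- config$com_upper; c2m <- config$com_fore
  m1 <- config$m_upper; m2 <- config$m_fore
  i1 <- config$i_upper; i2 <- config$i_fore
  gx <- config$gravity[1L]; gy <- config$gravity[2L]
  c2 <- cos(q[, 2L]); s2 <- sin(q[, 2L])
  m11 <- m1 * c1m^2 + i1 + m2 * (l1^2 + c2m^2 + 2 * l1 * c2m * c2) + i2
  m12 <- m2 * (c2m^2 + l1 * c2m * c2) + i2
  m22 <- m2 * c2m^2 + i2
  h <- m2 * l1 * c2m * s2
  cor1 <- -h * qd[, 2L]^2 - 2 * h * qd[, 1L] * qd[, 2L]
  cor2 <- h * qd[, 1L]^2
  # gravity torques: tau_g,j = -sum_i m_i * g . dp_com,i/dq_j
  c1 <- cos(q[, 1L]); s1 <- sin(q[, 1L])
  c12 <- cos(q[, 1L] + q[, 2L]); s12 <- sin(q[, 1L] + q[, 2L])
  g1 <- -(m1 * c1m + m2 * l1) * (gx * (-s1) + gy * c1) -
    m2 * c2m * (gx * (-s12) + gy * c12)
  g2 <- -m2 * c2m * (gx * (-s12) + gy * c12)
  cbind(m11 * qdd[, 1L] + m12 * qdd[, 2L] + cor1 + g1,
        m12 * qdd[, 1L] + m22 * qdd[, 2L] + cor2 + g2)
}

#' Forward simulation of propulsion cycles
#'
#' Integrates the 15 muscle activation states forward under periodic
#' spline-parameterized excitations while the closed chain prescribes the
#' kinematics (crank at constant speed on the given crank-length profile).
#' Several settling cycles are simulated so the periodic excitations drive
#' the activations to a cycle-stationary state; the last cycle is the
#' evaluation cycle.
#'
#' At each output time the simulator evaluates musculotendon lengths and
#' velocities from constant moment arms,
#' \eqn{L_{MT}(q) = L_{MT,0} - \sum_j r_j (q_j - q_{ref,j})}, the rigid-tendon
#' Hill forces, joint torques (moment-arm-weighted muscle forces plus
#' joint-limit torques), and the crank torque by virtual work:
#' \deqn{\tau_{crank} = \sum_j (\tau_{app,j} - \tau_{ID,j})\,
#'       \partial q_j / \partial\theta,}
#' with instantaneous power \eqn{\tau_{crank}\,\omega}. Fibers are at optimal
#' length at the reference posture \code{q_ref} (by default the
#' inverse-kinematics pose of the crank centre).
#'
#' @param profile a \code{\link{to_crank_length_profile}} object.
#' @param excitations n_muscles-by-n_nodes matrix of excitation control nodes
#'   in \code{[0, 1]} (rows in roster order), interpolated by periodic cubic
#'   splines over the cycle; or a list of functions \code{u(t)}.
#' @param muscles a \code{\link{muscle_set}}.
#' @param arm an \code{\link{arm_config}}.
#' @param mech a \code{\link{mechanism_config}}.
#' @param n_cycles total cycles to simulate (settling + 1 evaluation),
#'   default 4: three settling cycles then the evaluation cycle.
#' @param n_out output samples per cycle (multiple of 4 recommended so that
#'   propulsion-zone boundaries fall on grid points).
#' @param a0 initial activation (and implicit initial excitation) value.
#' @param q_ref reference posture (rad, length 2) at which fibers sit at
#'   optimal length; default the crank-centre pose.
#' @param branch elbow branch, see \code{\link{inverse_kinematics}}.
#' @param rtol,atol integrator tolerances (adaptive Runge-Kutta 4(5)).
#' @return Object of class \code{"propulsion_trace"}; see
#'   \code{\link{trace_cycle}}, \code{\link{net_propulsion_power}},
#'   \code{\link{energy_audit}}.
#' @export
simulate_cycles <- function(profile, excitations, muscles, arm, mech,
                            n_cycles = 4L, n_out = 240L, a0 = 0.050,
                            q_ref = NULL, branch = "auto",
                            rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(muscles, "muscle_set"), inherits(arm, "arm_config"),
            inherits(mech, "mechanism_config"))
  n_m <- nrow(muscles)
  period <- 2 * pi / mech$omega
  n_out <- as.integer(n_out)

  ufun <- if (is.list(excitations)) {
    if (length(excitations) != n_m) stop("need one excitation function per muscle")
    excitations
  } else {
    if (nrow(excitations) != n_m)
      stop("excitation matrix must have one row per muscle")
    lapply(seq_len(n_m), function(i)
      excitation_spline(excitations[i, ], period))
  }

  # one cycle of prescribed kinematics, reused periodically
  t1 <- seq(0, period, length.out = n_out + 1L)
  pose <- path_kinematics(profile, arm, mech, t1, branch = branch)
  if (is.null(q_ref))
    q_ref <- drop(inverse_kinematics(mech$center, arm, branch = branch)$q)

  cosa <- cos(muscles$penn_deg * pi / 180)
  l_mt0 <- muscles$L_slack_m + muscles$L_opt_m * cosa
  R <- cbind(muscles$r_shoulder_m, pose$branch * muscles$r_elbow_m)
  dq <- sweep(pose$q, 2L, q_ref, "-")
  l_mt1 <- matrix(l_mt0, n_out + 1L, n_m, byrow = TRUE) - dq %*% t(R)
  v_mt1 <- -pose$qd %*% t(R)
  slackless <- sweep(l_mt1, 2L, muscles$L_slack_m, "-") <= 0
  if (any(slackless))
    stop("simulation error: musculotendon length below tendon slack length for muscle '",
         muscles$name[which(slackless, arr.ind = TRUE)[1L, 2L]], "'")

  times <- seq(0, n_cycles * period, length.out = n_cycles * n_out + 1L)
  tau_a <- muscles$tau_act
  tau_d <- muscles$tau_deact
  deriv <- function(t, a, parms) {
    u <- vapply(ufun, function(f) f(t), numeric(1L))
    a <- pmin(pmax(a, 0), 1)
    tau <- ifelse(u > a, tau_a * (0.5 + 1.5 * a), tau_d / (0.5 + 1.5 * a))
    list((u - a) / tau)
  }
  sol <- tryCatch(
    deSolve::ode(y = rep(a0, n_m), times = times, func = deriv, parms = NULL,
                 method = "ode45", rtol = rtol, atol = atol),
    warning = function(w) stop("simulation error: integrator reported: ",
                               conditionMessage(w)),
    error = function(e) stop("simulation error: integrator failed: ",
                             conditionMessage(e)))
  a_mat <- unname(sol[, -1L, drop = FALSE])
  if (anyNA(a_mat)) stop("simulation error: integrator returned NA states")
  a_mat <- pmin(pmax(a_mat, 0), 1)

  idx <- rep(seq_len(n_out), n_cycles)               # cycle-position index
  idx <- c(idx, n_out + 1L)
  n_t <- length(times)
  l_mt <- l_mt1[idx, , drop = FALSE]
  v_mt <- v_mt1[idx, , drop = FALSE]
  force <- matrix(0, n_t, n_m)
  for (i in seq_len(n_m))
    force[, i] <- musculotendon_force(as.list(muscles[i, ]), a_mat[, i],
                                      l_mt[, i], v_mt[, i])
  lnorm <- sweep(sweep(l_mt, 2L, muscles$L_slack_m, "-"), 2L,
                 muscles$L_opt_m * cosa, "/")
  vnorm <- sweep(sweep(v_mt, 2L, cosa, "/"), 2L, muscles$L_opt_m, "/")

  q <- pose$q[idx, , drop = FALSE]
  qd <- pose$qd[idx, , drop = FALSE]
  tau_musc <- force %*% R
  tau_lim <- joint_limit_torque(q, qd, arm, pose$branch)
  tau_id <- inverse_dynamics(pose, arm)[idx, , drop = FALSE]
  power <- rowSums((tau_musc + tau_lim - tau_id) * qd)
  tau_crank <- power / mech$omega

  structure(list(time = times, theta = pose$theta[idx],
                 cycle = c(rep(seq_len(n_cycles), each = n_out), n_cycles),
                 q = q, qd = qd, flexion_deg = pose$flexion_deg[idx],
                 a = a_mat, force = force,
                 l_mt = l_mt, v_mt = v_mt, lnorm = lnorm, vnorm = vnorm,
                 tau_muscle = tau_musc, tau_limit = tau_lim, tau_id = tau_id,
                 tau_crank = tau_crank, power = power,
                 range_excursion = pose$range_excursion[idx, , drop = FALSE],
                 period = period, n_out = n_out, n_cycles = n_cycles,
                 eval_cycle = n_cycles, branch = pose$branch,
                 muscles = muscles, arm = arm, mech = mech),
            class = "propulsion_trace")
}

#' @export
print.propulsion_trace <- function(x, ...) {
  cat(sprintf("Propulsion trace: %d cycles x %d samples, %d muscles, %.1f rpm\n",
              x$n_cycles, x$n_out, ncol(x$a), x$mech$omega_rpm))
  cat(sprintf("  net power (evaluation cycle %d): %.3f W\n",
              x$eval_cycle, net_propulsion_power(x)))
  invisible(x)
}

#' Extract one cycle from a propulsion trace
#'
#' @param trace a \code{\link{simulate_cycles}} trace.
#' @param cycle cycle number (default the evaluation cycle, i.e. the last).
#' @return A \code{"propulsion_trace"} restricted to that cycle, including
#'   both of its endpoints.
#' @export
trace_cycle <- function(trace, cycle = trace$eval_cycle) {
  stopifnot(inherits(trace, "propulsion_trace"),
            cycle >= 1L, cycle <= trace$n_cycles)
  i <- ((cycle - 1L) * trace$n_out + 1L):(cycle * trace$n_out + 1L)
  out <- trace
  vec <- c("time", "theta", "cycle", "flexion_deg", "tau_crank", "power")
  mat <- c("q", "qd", "a", "force", "l_mt", "v_mt", "lnorm", "vnorm",
           "tau_muscle", "tau_limit", "tau_id", "range_excursion")
  for (f in vec) out[[f]] <- trace[[f]][i]
  for (f in mat) out[[f]] <- trace[[f]][i, , drop = FALSE]
  out$n_cycles <- 1L
  out$eval_cycle <- 1L
  out
}

#' Net propulsion power of a trace
#'
#' Time-average of the instantaneous crank power over the evaluation cycle.
#'
#' @param trace a \code{\link{simulate_cycles}} trace.
#' @param cycle cycle to evaluate (default the evaluation cycle).
#' @return Net power (W).
#' @export
net_propulsion_power <- function(trace, cycle = trace$eval_cycle) {
  cyc <- if (trace$n_cycles == 1L) trace else trace_cycle(trace, cycle)
  net_power(cyc$time, cyc$power, trace$period)
}

#' Energy audit of one propulsion cycle
#'
#' Decomposes the net crank work over a cycle into musculotendon work,
#' joint-limit (passive-element) work and rigid-body (inverse-dynamics) work.
#' Over a periodic cycle the rigid-body work vanishes (no net change of
#' kinetic or potential energy), so crank work must equal musculotendon plus
#' passive work up to quadrature error.
#'
#' @param trace a \code{\link{simulate_cycles}} trace.
#' @param cycle cycle to audit (default the evaluation cycle).
#' @return List with \code{crank}, \code{muscle}, \code{limit}, \code{rigid}
#'   work terms (J) and the balance \code{residual} (J):
#'   crank - (muscle + limit - rigid).
#' @export
energy_audit <- function(trace, cycle = trace$eval_cycle) {
  cyc <- if (trace$n_cycles == 1L) trace else trace_cycle(trace, cycle)
  tt <- cyc$time
  w_crank <- pracma::trapz(tt, cyc$power)
  w_muscle <- sum(vapply(seq_len(ncol(cyc$force)), function(i)
    pracma::trapz(tt, -cyc$force[, i] * cyc$v_mt[, i]), numeric(1L)))
  w_limit <- pracma::trapz(tt, rowSums(cyc$tau_limit * cyc$qd))
  w_rigid <- pracma::trapz(tt, rowSums(cyc$tau_id * cyc$qd))
  list(crank = w_crank, muscle = w_muscle, limit = w_limit, rigid = w_rigid,
       residual = w_crank - (w_muscle + w_limit - w_rigid))
}
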