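#' Crank-slider mechanism configuration
#'
#' The propulsion mechanism is a crank rotating at constant angular velocity
#' about a fixed centre, carrying a slider that varies the effective crank
#' length, with the handle pinned to the slider. Propulsion is isokinetic:
#' the crank speed is imposed (ergometer-like), 50 rpm by default.
#'
#' @param center crank centre (x, y) in metres, global frame (origin at the
#'   sternum). See \code{\link{place_crank_center}} for the anthropometric
#'   placement rule.
#' @param omega_rpm constant crank speed in revolutions per minute (> 0).
#' @param sense rotation sense, \code{"cw"} (propulsion convention) or
#'   \code{"ccw"}.
#' @param cl_bounds slider travel limits (m).
#' @return Object of class \code{"mechanism_config"}. The field \code{omega}
#'   holds the speed in rad/s.
#' @export
mechanism_config <- function(center = c(0.25, -0.44), omega_rpm = 50,
                             sense = c("cw", "ccw"),
                             cl_bounds = c(0.030, 0.155)) {
  sense <- match.arg(sense)
  stopifnot(is.numeric(center), length(center) == 2L,
            is.numeric(omega_rpm), length(omega_rpm) == 1L)
  if (omega_rpm <= 0) stop("'omega_rpm' must be positive")
  if (cl_bounds[1L] <= 0 || cl_bounds[2L] <= cl_bounds[1L])
    stop("'cl_bounds' must be increasing and positive")
  structure(list(center = as.numeric(center),
                 omega = omega_rpm * 2 * pi / 60,
                 omega_rpm = omega_rpm,
                 sense = sense,
                 cl_bounds = cl_bounds),
            class = "mechanism_config")
}

#' @export
print.mechanism_config <- function(x, ...) {
  cat(sprintf("Crank-slider mechanism: centre (%.3f, %.3f) m, %.1f rpm %s, CL in [%.3f, %.3f] m\n",
              x$center[1L], x$center[2L], x$omega_rpm, x$sense,
              x$cl_bounds[1L], x$cl_bounds[2L]))
  invisible(x)
}

#' Anthropometric placement of the crank centre
#'
#' The crank centre x coordinate is the midpoint between the wheelchair seat
#' reference point and the knee joint; its y coordinate is the forearm height
#' above the seat reference point with the elbow flexed at 90 degrees.
#'
#' @param srp seat reference point (x, y) in metres, global frame.
#' @param knee knee joint position (x, y) in metres.
#' @param forearm_height vertical distance (m) from the seat reference point
#'   to the forearm with the elbow at 90 degrees.
#' @return Crank centre as a length-2 numeric vector (m).
#' @export
place_crank_center <- function(srp, knee, forearm_height) {
  stopifnot(length(srp) == 2L, length(knee) == 2L,
            is.numeric(forearm_height), length(forearm_height) == 1L)
  c((srp[1L] + knee[1L]) / 2, srp[2L] + forearm_height)
}

# Unit vector of the crank at propulsion-sense angle phi; sense "cw" maps
# increasing phi to clockwise motion in the global x-y plane.
.crank_unit <- function(phi, sense) {
  s <- if (sense == "cw") -1 else 1
  cbind(cos(s * phi), sin(s * phi))
}

#' Crank-slider kinematics at given times
#'
#' The crank angle advances as \eqn{\theta(t) = \omega t} in the rotation
#' sense, from the positive x axis of the crank frame; the slider sets the
#' effective crank length from the profile; the handle sits at the slider
#' pin. Velocities follow from the chain rule through the profile
#' interpolant.
#'
#' @param profile a \code{\link{to_crank_length_profile}} object.
#' @param config a \code{\link{mechanism_config}}.
#' @param t time(s) in seconds (>= 0).
#' @return List of class \code{"crank_state"}: \code{t}, \code{theta}
#'   (wrapped to \code{[0, 2*pi)}), \code{CL} (m), \code{pos} and \code{vel}
#'   (n-by-2 matrices, global frame, m and m/s).
#' @export
crank_kinematics <- function(profile, config, t) {
  stopifnot(inherits(profile, "crank_length_profile"),
            inherits(config, "mechanism_config"), is.numeric(t))
  if (any(t < 0)) stop("'t' must be non-negative")
  theta <- (config$omega * t) %% (2 * pi)
  cl <- profile_eval(profile, theta)
  dcl <- profile_eval(profile, theta, deriv = 1L)
  s <- if (config$sense == "cw") -1 else 1
  u <- .crank_unit(theta, config$sense)
  # tangent of the unit vector w.r.t. theta
  du <- cbind(-s * sin(s * theta), s * cos(s * theta))
  pos <- sweep(cl * u, 2L, config$center, "+")
  vel <- config$omega * (dcl * u + cl * du)
  structure(list(t = t, theta = theta, CL = cl, pos = pos, vel = vel),
            class = "crank_state")
}

#' Crank torque from a handle force
#'
#' The z-moment of the handle force about the crank centre, with the sign
#' convention that positive torque drives the crank in its propulsion
#' (rotation-sense) direction.
#'
#' @param force force at the handle, (Fx, Fy) in newtons, global frame; or an
#'   n-by-2 matrix.
#' @param state a \code{\link{crank_kinematics}} state (its \code{pos} is the
#'   point of application).
#' @param config a \code{\link{mechanism_config}}.
#' @return Torque(s) in newton-metres, propulsion-positive.
#' @export
crank_torque <- function(force, state, config) {
  stopifnot(inherits(state, "crank_state"), inherits(config, "mechanism_config"))
  f <- if (is.matrix(force)) force else matrix(force, ncol = 2L)
  r <- sweep(state$pos, 2L, config$center, "-")
  tau_z <- r[, 1L] * f[, 2L] - r[, 2L] * f[, 1L]
  if (config$sense == "cw") -tau_z else tau_z
}

#' Instantaneous crank power
#'
#' Product of the instantaneous crank torque and the (constant) crank
#' angular speed.
#'
#' @param torque torque(s) in newton-metres, propulsion-positive.
#' @param config a \code{\link{mechanism_config}}.
#' @return Power in watts.
#' @export
instantaneous_power <- function(torque, config) {
  stopifnot(inherits(config, "mechanism_config"))
  torque * config$omega
}

#' Net propulsion power over one crank cycle
#'
#' Time-average of the instantaneous power over exactly one propulsion cycle,
#' by trapezoidal quadrature.
#'
#' @param time strictly increasing time grid (s) spanning one cycle.
#' @param power instantaneous power (W) on that grid.
#' @param period cycle duration (s); the grid span must match it to within
#'   0.1 percent.
#' @return Net power in watts.
#' @export
net_power <- function(time, power, period) {
  stopifnot(is.numeric(time), is.numeric(power), length(time) == length(power),
            length(time) >= 2L, is.numeric(period), length(period) == 1L)
  span <- time[length(time)] - time[1L]
  if (abs(span - period) > 1e-3 * period)
    stop(sprintf("series spans %.6f s but one cycle is %.6f s", span, period))
  pracma::trapz(time, power) / span
}
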