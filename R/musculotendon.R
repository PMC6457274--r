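#' Hill-type musculotendon actuators
#'
#' The muscle model follows the standard Hill-type formulation with
#' first-order excitation-to-activation dynamics, a Gaussian active
#' force-length curve, an exponential passive force-length curve and a
#' hyperbolic/saturating force-velocity curve, reduced to a rigid tendon:
#' the fiber length is algebraic in the musculotendon length,
#' \eqn{L_{fiber} \cos\alpha = L_{MT} - L_{slack}}, which halves the state
#' dimension and is accurate for the short-tendon upper-limb muscles at
#' propulsion cadence. Only the 15 activations remain as dynamic states.
#'
#' @name musculotendon
NULL

# Curve constants (Thelen-2003-style): activation/deactivation time
# constants, force-length Gaussian width, passive curve shape and maximum
# strain, eccentric plateau and concentric curvature.
.mt_defaults <- list(tau_act = 0.010, tau_deact = 0.040,
                     fl_width = 0.45, pe_shape = 4, pe_strain_max = 0.6,
                     f_len = 1.4, a_f = 0.25, v_max = 10)

#' Activation rate of a muscle
#'
#' First-order excitation-to-activation dynamics with activation-dependent
#' time constant: activation rises faster at high activation and decays
#' faster at low activation,
#' \eqn{da/dt = (u - a)/\tau}, with
#' \eqn{\tau = \tau_{act}(0.5 + 1.5a)} when \eqn{u > a} and
#' \eqn{\tau = \tau_{deact}/(0.5 + 1.5a)} otherwise.
#'
#' Inputs outside \code{[0, 1]} are clamped with a warning.
#'
#' @param u neural excitation in \code{[0, 1]} (vectorized).
#' @param a activation in \code{[0, 1]} (vectorized).
#' @param tau_act,tau_deact activation/deactivation time constants (s).
#' @return da/dt in 1/s.
#' @export
activation_rate <- function(u, a, tau_act = 0.010, tau_deact = 0.040) {
  if (any(u < 0 | u > 1) || any(a < 0 | a > 1)) {
    warning("excitation/activation outside [0, 1]; clamping")
    u <- pmin(pmax(u, 0), 1)
    a <- pmin(pmax(a, 0), 1)
  }
  tau <- ifelse(u > a, tau_act * (0.5 + 1.5 * a), tau_deact / (0.5 + 1.5 * a))
  (u - a) / tau
}

#' Active force-length scale
#'
#' Gaussian curve with maximum 1 at the optimal fiber length.
#'
#' @param lnorm normalized fiber length (fiber length / optimal fiber
#'   length), > 0.
#' @param width Gaussian width parameter.
#' @return Scale in \code{[0, 1]}.
#' @export
active_force_length <- function(lnorm, width = 0.45) {
  exp(-(lnorm - 1)^2 / width)
}

#' Passive force-length scale
#'
#' Exponential passive curve: zero at or below the optimal fiber length,
#' rising to 1 at the maximum passive strain (default 60 percent beyond
#' optimal).
#'
#' @param lnorm normalized fiber length, > 0.
#' @param strain_max strain at which the passive force equals the maximum
#'   isometric force.
#' @param shape exponential shape factor.
#' @return Scale >= 0.
#' @export
passive_force_length <- function(lnorm, strain_max = 0.6, shape = 4) {
  pmax(0, expm1(shape * (lnorm - 1) / strain_max) / expm1(shape))
}

#' Force-velocity scale
#'
#' Hyperbolic (Hill) concentric branch falling to 0 at the maximum
#' shortening velocity, and a smooth eccentric branch saturating at the
#' lengthening plateau \code{f_len}; the two branches meet with matching
#' value (1) and slope at zero velocity.
#'
#' @param vnorm fiber velocity in optimal fiber lengths per second;
#'   shortening is negative.
#' @param v_max maximum shortening velocity (optimal fiber lengths per
#'   second), default 10.
#' @param f_len eccentric force plateau (default 1.4).
#' @param a_f concentric curvature constant (default 0.25).
#' @return Scale >= 0.
#' @export
force_velocity <- function(vnorm, v_max = 10, f_len = 1.4, a_f = 0.25) {
  v <- vnorm / v_max
  slope0 <- 1 + 1 / a_f
  conc <- pmax(0, (1 + pmax(v, -1)) / (1 - pmax(v, -1) / a_f))
  ecc <- f_len - (f_len - 1) * exp(-v * slope0 / (f_len - 1))
  ifelse(v > 0, ecc, conc)
}

#' Rigid-tendon musculotendon force
#'
#' Fiber length and velocity follow algebraically from the musculotendon
#' length under a rigid tendon and constant pennation:
#' \eqn{L_{fiber} = (L_{MT} - L_{slack}) / \cos\alpha},
#' \eqn{V_{fiber} = V_{MT} / \cos\alpha}. The tendon force is
#' \deqn{F = F_{iso,max}\,[a\,f_L(\tilde L)\,f_V(\tilde V) + f_P(\tilde L)]\cos\alpha,}
#' clamped to be non-negative.
#'
#' @param params one row of a \code{\link{default_muscles}} table (list or
#'   one-row data frame) with fields \code{F_iso_max_N}, \code{L_opt_m},
#'   \code{L_slack_m}, \code{penn_deg} and optionally \code{v_max}.
#' @param a activation in \code{[0, 1]} (vectorized).
#' @param l_mt musculotendon length(s) (m).
#' @param v_mt musculotendon lengthening velocity (m/s; shortening
#'   negative).
#' @return Tendon force in newtons (>= 0), same length as the longest input.
#' @export
musculotendon_force <- function(params, a, l_mt, v_mt = 0) {
  cosa <- cos(params$penn_deg * pi / 180)
  lf <- (l_mt - params$L_slack_m) / cosa
  if (any(lf <= 0))
    stop(sprintf("muscle '%s': musculotendon length %.4f m leaves no fiber length",
                 params$name, min(l_mt)))
  v_max <- if (!is.null(params$v_max)) params$v_max else .mt_defaults$v_max
  lnorm <- lf / params$L_opt_m
  vnorm <- (v_mt / cosa) / params$L_opt_m
  f <- params$F_iso_max_N *
    (a * active_force_length(lnorm) * force_velocity(vnorm, v_max) +
       passive_force_length(lnorm)) * cosa
  pmax(f, 0)
}

#' The 15-muscle actuator roster
#'
#' Loads the packaged synthetic muscle parameter table: the 15 upper-limb
#' musculotendon actuators spanning shoulder, elbow and wrist (three deltoid
#' compartments, long/short biceps, long/lateral triceps, brachialis, two
#' wrist flexors, pectoralis major and the four rotator-cuff muscles). The
#' values are literature-plausible magnitudes for a 50th-percentile adult
#' male, shipped as a synthetic fixture, not measurements. Moment arms are
#' constant per muscle-joint pair (planar reduction): positive means the
#' muscle shortens as the joint coordinate increases.
#'
#' @param file optional path to an alternative CSV with the same columns
#'   (\code{name,F_iso_max_N,L_opt_m,L_slack_m,penn_deg,r_shoulder_m,r_elbow_m,r_wrist_m}).
#' @return A data frame of class \code{"muscle_set"}, 15 rows in roster
#'   order, with activation-dynamics and force-velocity constants attached.
#' @export
default_muscles <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "muscle_params_synthetic.csv",
                        package = "hbpsim", mustWork = TRUE)
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  muscle_set(tab)
}

#' Construct a validated muscle set
#'
#' @param tab data frame with the columns described in
#'   \code{\link{default_muscles}}.
#' @param tau_act,tau_deact activation time constants (s) applied to all
#'   muscles.
#' @param v_max maximum shortening velocity (optimal fiber lengths per
#'   second).
#' @return A \code{"muscle_set"} data frame.
#' @export
muscle_set <- function(tab, tau_act = 0.010, tau_deact = 0.040, v_max = 10) {
  need <- c("name", "F_iso_max_N", "L_opt_m", "L_slack_m", "penn_deg",
            "r_shoulder_m", "r_elbow_m", "r_wrist_m")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("muscle table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$name)) stop("muscle names must be unique")
  num <- c("F_iso_max_N", "L_opt_m", "L_slack_m")
  if (any(as.matrix(tab[num]) <= 0)) stop("forces and lengths must be positive")
  if (any(tab$penn_deg < 0 | tab$penn_deg >= 90))
    stop("pennation angles must lie in [0, 90) degrees")
  tab$tau_act <- tau_act
  tab$tau_deact <- tau_deact
  tab$v_max <- v_max
  class(tab) <- c("muscle_set", "data.frame")
  tab
}

#' @export
print.muscle_set <- function(x, ...) {
  cat(sprintf("Muscle set: %d Hill-type actuators (rigid tendon)\n", nrow(x)))
  print.data.frame(x[, c("name", "F_iso_max_N", "L_opt_m", "L_slack_m",
                         "penn_deg", "r_shoulder_m", "r_elbow_m")], ...)
  invisible(x)
}
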