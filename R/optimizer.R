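#' Periodic excitation spline
#'
#' Builds the periodic cubic-spline excitation signal through control nodes
#' placed at equal time fractions of the propulsion cycle. The first node
#' serves as both endpoints of the cycle, which enforces the periodicity of
#' the muscle activity pattern structurally. Spline overshoot is clipped to
#' \code{[0, 1]}.
#'
#' @param nodes excitation control-node values in \code{[0, 1]}.
#' @param period cycle duration (s).
#' @return A function \code{u(t)} valid for any t (periodic).
#' @export
excitation_spline <- function(nodes, period) {
  stopifnot(is.numeric(nodes), length(nodes) >= 2L, period > 0)
  if (any(nodes < 0 | nodes > 1)) stop("excitation nodes must lie in [0, 1]")
  k <- length(nodes)
  f <- stats::splinefun(seq(0, period, length.out = k + 1L),
                        c(nodes, nodes[1L]), method = "periodic")
  function(t) pmin(pmax(f(t %% period), 0), 1)
}

#' Evaluate a periodic excitation signal
#'
#' @param nodes excitation control-node values in \code{[0, 1]}.
#' @param t time(s) in seconds.
#' @param period cycle duration (s).
#' @return Excitation value(s) in \code{[0, 1]}.
#' @export
excitation_signal <- function(nodes, t, period) {
  excitation_spline(nodes, period)(t)
}

#' Assemble the optimization control vector
#'
#' Flattens per-muscle excitation nodes and the four shape parameters into
#' the optimization vector: muscles in roster order (all nodes of muscle 1,
#' then muscle 2, ...), followed by A, B, n and the tilt angle beta (rad).
#' With the full 15-muscle roster and 10 nodes per muscle this yields 154
#' variables.
#'
#' @param excitations n_muscles-by-n_nodes matrix of nodes in \code{[0, 1]};
#'   row names, if present, are carried into the vector names.
#' @param shape a \code{\link{path_shape}}.
#' @return Named numeric vector with attributes \code{n_muscles} and
#'   \code{n_nodes}.
#' @export
assemble_controls <- function(excitations, shape) {
  stopifnot(is.matrix(excitations), inherits(shape, "path_shape"))
  n_m <- nrow(excitations)
  n_k <- ncol(excitations)
  who <- rownames(excitations)
  if (is.null(who)) who <- paste0("m", seq_len(n_m))
  x <- c(as.vector(t(excitations)), shape$A, shape$B, shape$n, shape$beta)
  names(x) <- c(paste0(rep(who, each = n_k), "_u", seq_len(n_k)),
                "A", "B", "n", "beta")
  structure(x, n_muscles = n_m, n_nodes = n_k)
}

#' Disassemble a control vector
#'
#' @param x a vector from \code{\link{assemble_controls}}, or any numeric
#'   vector of length \code{n_muscles * n_nodes + 4}.
#' @param n_muscles,n_nodes layout; taken from the vector's attributes when
#'   present.
#' @return List with \code{excitations} (matrix) and \code{shape}
#'   (\code{\link{path_shape}}).
#' @export
disassemble_controls <- function(x, n_muscles = attr(x, "n_muscles"),
                                 n_nodes = attr(x, "n_nodes")) {
  if (is.null(n_muscles) || is.null(n_nodes))
    stop("control-vector layout unknown; supply 'n_muscles' and 'n_nodes'")
  if (length(x) != n_muscles * n_nodes + 4L)
    stop(sprintf("control vector has length %d, expected %d",
                 length(x), n_muscles * n_nodes + 4L))
  exc <- matrix(unname(x[seq_len(n_muscles * n_nodes)]), n_muscles, n_nodes,
                byrow = TRUE)
  s <- unname(x[n_muscles * n_nodes + 1:4])
  list(excitations = exc,
       shape = path_shape(s[1L], s[2L], s[3L], beta_deg = s[4L] * 180 / pi))
}

#' Bounds of the control vector
#'
#' @param n_muscles,n_nodes control layout.
#' @param beta_bounds_deg tilt-angle bounds in degrees (default +/- 90).
#' @param cl_bounds slider travel limits bounding A and B (m).
#' @return List with \code{lower} and \code{upper} numeric vectors.
#' @export
control_bounds <- function(n_muscles = 15L, n_nodes = 10L,
                           beta_bounds_deg = c(-90, 90),
                           cl_bounds = c(0.030, 0.155)) {
  n_u <- n_muscles * n_nodes
  list(lower = c(rep(0, n_u), cl_bounds[1L], cl_bounds[1L], 0,
                 beta_bounds_deg[1L] * pi / 180),
       upper = c(rep(1, n_u), cl_bounds[2L], cl_bounds[2L], 1,
                 beta_bounds_deg[2L] * pi / 180))
}

#' Optimization problem setup
#'
#' Bundles the model configuration, control layout, simulation protocol and
#' penalty weights of the propulsion optimization.
#'
#' @param muscles a \code{\link{muscle_set}} (default the packaged 15-muscle
#'   roster).
#' @param arm an \code{\link{arm_config}}.
#' @param mech a \code{\link{mechanism_config}}.
#' @param n_nodes excitation control nodes per muscle (default 10).
#' @param n_cycles settling + evaluation cycles (default 4: three settling
#'   cycles, then the evaluation cycle).
#' @param n_out output samples per cycle.
#' @param n_path path polyline samples.
#' @param a0 initial activation value.
#' @param branch elbow branch.
#' @param weights penalty weights: \code{joint_range} (per rad^2 s of
#'   excursion), \code{shape} (unreachable / non-star-shaped indicator),
#'   \code{cl} (per m^2 of crank-length bound excursion).
#' @param beta_bounds_deg tilt-angle bounds (degrees).
#' @return List of class \code{"propulsion_setup"}.
#' @export
propulsion_setup <- function(muscles = default_muscles(),
                             arm = arm_config(),
                             mech = mechanism_config(),
                             n_nodes = 10L, n_cycles = 4L, n_out = 240L,
                             n_path = 720L, a0 = 0.050, branch = "auto",
                             weights = list(joint_range = 100,
                                            shape = 1e4, cl = 1e3),
                             beta_bounds_deg = c(-90, 90)) {
  structure(list(muscles = muscles, arm = arm, mech = mech,
                 n_nodes = as.integer(n_nodes),
                 n_cycles = as.integer(n_cycles),
                 n_out = as.integer(n_out), n_path = as.integer(n_path),
                 a0 = a0, branch = branch, weights = weights,
                 beta_bounds_deg = beta_bounds_deg),
            class = "propulsion_setup")
}

#' Net-power-with-penalties objective
#'
#' Builds the handle path from the shape part of the control vector, runs the
#' settling and evaluation cycles, and returns the minimization objective:
#' negative net propulsion power plus quadratic penalties for joint-range
#' excursions and crank-length-bound excursions, and an indicator penalty for
#' geometrically infeasible shapes (non-star-shaped or unreachable), which
#' are rejected without simulation.
#'
#' A simulation failure yields a large finite objective with the
#' \code{failed} flag set, so search backends can continue.
#'
#' @param x control vector (see \code{\link{assemble_controls}}); layout
#'   taken from \code{setup}.
#' @param setup a \code{\link{propulsion_setup}}.
#' @return List of class \code{"objective_report"}: \code{total},
#'   \code{net_power} (W, \code{NA} if not simulated), \code{penalties}
#'   (list: \code{joint_range}, \code{shape}, \code{cl_bounds}),
#'   \code{feasible}, \code{failed}.
#' @export
propulsion_objective <- function(x, setup) {
  stopifnot(inherits(setup, "propulsion_setup"))
  d <- disassemble_controls(x, nrow(setup$muscles), setup$n_nodes)
  w <- setup$weights
  report <- function(total, net = NA_real_, pq = 0, ps = 0, pc = 0,
                     feasible = TRUE, failed = FALSE)
    structure(list(total = total, net_power = net,
                   penalties = list(joint_range = pq, shape = ps,
                                    cl_bounds = pc),
                   feasible = feasible, failed = failed),
              class = "objective_report")

  poly <- sample_path(d$shape, setup$n_path)
  if (!poly$star_shaped)
    return(report(w$shape, ps = w$shape, feasible = FALSE))

  # reachability of every handle point (global frame)
  hp <- sweep(poly$xy, 2L, setup$mech$center, "+")
  dist <- sqrt((hp[, 1L] - setup$arm$shoulder[1L])^2 +
                 (hp[, 2L] - setup$arm$shoulder[2L])^2)
  lo <- abs(setup$arm$l_upper - setup$arm$l_fore)
  hi <- setup$arm$l_upper + setup$arm$l_fore
  exc <- max(pmax(0, dist - hi), pmax(0, lo - dist))
  if (exc > 0)
    return(report(w$shape * (1 + exc), ps = w$shape * (1 + exc),
                  feasible = FALSE))

  profile <- to_crank_length_profile(poly, sense = setup$mech$sense,
                                     bounds = setup$mech$cl_bounds,
                                     check_bounds = FALSE)
  over <- pmax(0, profile$CL - setup$mech$cl_bounds[2L]) +
    pmax(0, setup$mech$cl_bounds[1L] - profile$CL)
  pen_cl <- w$cl * mean(over^2)

  trace <- tryCatch(
    simulate_cycles(profile, d$excitations, setup$muscles, setup$arm,
                    setup$mech, n_cycles = setup$n_cycles,
                    n_out = setup$n_out, a0 = setup$a0,
                    branch = setup$branch),
    error = function(e) e)
  if (inherits(trace, "error"))
    return(report(1e6, pc = pen_cl, feasible = FALSE, failed = TRUE))

  cyc <- trace_cycle(trace)
  pen_q <- w$joint_range *
    pracma::trapz(cyc$time, rowSums(cyc$range_excursion^2))
  net <- net_propulsion_power(trace)
  report(-net + pen_q + pen_cl, net = net, pq = pen_q, pc = pen_cl,
         feasible = pen_q == 0 && pen_cl == 0)
}

#' @export
print.objective_report <- function(x, ...) {
  cat(sprintf("Objective %.4f (net power %.3f W; penalties: joint %.3g, shape %.3g, CL %.3g)%s\n",
              x$total, x$net_power, x$penalties$joint_range,
              x$penalties$shape, x$penalties$cl_bounds,
              if (x$failed) " [simulation failed]" else ""))
  invisible(x)
}

#' Dynamic optimization of shape and excitations
#'
#' Jointly optimizes the handle-path shape parameters and the per-muscle
#' excitation node values to maximize net propulsion power (minimize the
#' penalized objective). The backend is a (1+1) evolution strategy with
#' per-dimension steps scaled to the bound widths and a 1/5-success-rule
#' step-size adaptation: gradient-free, robust to the mild noise-like
#' roughness the adaptive integrator induces, and exactly reproducible for a
#' given seed. The terminal condition (crank angle 360 degrees at the final
#' time) and the excitation periodicity constraint hold by construction: the
#' crank angle is prescribed as \eqn{\omega t} over one period and the
#' excitation splines are periodic.
#'
#' @param setup a \code{\link{propulsion_setup}}.
#' @param seed integer seed for the random initial controls and the search.
#' @param n_iter number of objective evaluations after the initial one.
#' @param sigma0 initial step size as a fraction of each bound width.
#' @param x0 optional initial control vector; by default drawn uniformly
#'   within bounds.
#' @param objective objective function \code{f(x, setup)} returning a list
#'   with at least \code{total}; defaults to
#'   \code{\link{propulsion_objective}}.
#' @return List of class \code{"propulsion_fit"}: \code{par} (best control
#'   vector), \code{report} (its objective report), \code{history} (data
#'   frame of accepted iterates: evaluation index, total, net power),
#'   \code{initial_report}, \code{n_eval}, \code{seed}, \code{converged}
#'   (FALSE when the search was still improving at the end of the budget).
#' @export
optimize_propulsion <- function(setup, seed = 1L, n_iter = 200L,
                                sigma0 = 0.15, x0 = NULL,
                                objective = propulsion_objective) {
  stopifnot(inherits(setup, "propulsion_setup"))
  b <- control_bounds(nrow(setup$muscles), setup$n_nodes,
                      setup$beta_bounds_deg, setup$mech$cl_bounds)
  d <- length(b$lower)
  width <- b$upper - b$lower
  set.seed(as.integer(seed))
  if (is.null(x0)) x0 <- b$lower + stats::runif(d) * width
  if (length(x0) != d) stop("'x0' has the wrong length")
  x0 <- pmin(pmax(x0, b$lower), b$upper)

  best_x <- x0
  best <- objective(x0, setup)
  initial <- best
  hist <- data.frame(eval = 0L, total = best$total,
                     net_power = if (is.null(best$net_power)) NA_real_
                                 else best$net_power)
  sigma <- sigma0
  last_accept <- 0L
  for (k in seq_len(n_iter)) {
    y <- best_x + sigma * width * stats::rnorm(d)
    y <- pmin(pmax(y, b$lower), b$upper)
    rep_y <- objective(y, setup)
    if (rep_y$total <= best$total) {
      best_x <- y
      best <- rep_y
      last_accept <- k
      hist <- rbind(hist, data.frame(
        eval = k, total = rep_y$total,
        net_power = if (is.null(rep_y$net_power)) NA_real_
                    else rep_y$net_power))
      sigma <- min(sigma * 1.5, 1)
    } else {
      sigma <- max(sigma * 1.5^(-0.25), 1e-4)
    }
  }
  converged <- last_accept <= floor(0.9 * n_iter)
  if (!converged)
    warning("optimization still improving at the end of the evaluation budget; ",
            "returning best-so-far")
  structure(list(par = stats::setNames(best_x, names(x0)), report = best,
                 history = hist, initial_report = initial,
                 n_eval = n_iter + 1L, seed = as.integer(seed),
                 converged = converged),
            class = "propulsion_fit")
}

#' @export
print.propulsion_fit <- function(x, ...) {
  cat(sprintf("Propulsion optimization (seed %d, %d evaluations, %d accepted)\n",
              x$seed, x$n_eval, nrow(x$history)))
  print(x$report)
  invisible(x)
}
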