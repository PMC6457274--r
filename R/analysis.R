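#' Propulsion-zone partition of the crank cycle
#'
#' Divides one crank revolution into four zones (quadrants of the crank
#' angle, measured in the propulsion sense from the configured offset).
#' Zones 1 and 4 form the pull phase, zones 2 and 3 the push phase.
#'
#' @param offset_deg crank angle (degrees) at which zone 1 starts.
#' @return Object of class \code{"zone_partition"}: \code{breaks} (rad,
#'   length 5), \code{labels}, \code{phase} (pull/push per zone).
#' @export
zone_partition <- function(offset_deg = 0) {
  off <- offset_deg * pi / 180
  structure(list(breaks = off + seq(0, 2 * pi, length.out = 5L),
                 labels = paste0("zone", 1:4),
                 phase = c("pull", "push", "push", "pull")),
            class = "zone_partition")
}

# zone index (1..4) of crank angles, relative to the partition offset
.zone_of <- function(theta, zones) {
  rel <- (theta - zones$breaks[1L]) %% (2 * pi)
  pmin(1L + floor(rel / (pi / 2)), 4L)
}

#' Net muscle work per propulsion zone
#'
#' Mechanical work of each musculotendon unit over the evaluation cycle,
#' partitioned by the crank-angle zones: \eqn{W = \int F_{MT} \,
#' (-dL_{MT}/dt)\, dt} (shortening produces positive work), by trapezoidal
#' quadrature on the trace grid. Each inter-sample segment is assigned to
#' the zone of its midpoint crank angle, so the four zone works sum exactly
#' to the cycle total.
#'
#' @param trace a \code{\link{simulate_cycles}} trace (evaluation cycle is
#'   used; pass a \code{\link{trace_cycle}} extract for other cycles).
#' @param zones a \code{\link{zone_partition}}.
#' @return Object of class \code{"muscle_work_report"}: \code{work} (muscles
#'   by zones, J), \code{positive}/\code{negative} components, \code{total}
#'   (per-muscle cycle work, J) and the partition.
#' @export
muscle_work <- function(trace, zones = zone_partition()) {
  stopifnot(inherits(trace, "propulsion_trace"),
            inherits(zones, "zone_partition"))
  cyc <- if (trace$n_cycles == 1L) trace else trace_cycle(trace)
  span <- cyc$time[length(cyc$time)] - cyc$time[1L]
  if (abs(span - trace$period) > 1e-3 * trace$period)
    stop("trace does not span exactly one propulsion cycle")
  n <- length(cyc$time)
  dt <- diff(cyc$time)
  p <- -cyc$force * cyc$v_mt                       # shortening power, W
  seg <- (p[-n, , drop = FALSE] + p[-1L, , drop = FALSE]) / 2 * dt
  mid <- cyc$theta[-n] + dt * trace$mech$omega / 2
  zi <- .zone_of(mid, zones)
  n_m <- ncol(p)
  who <- trace$muscles$name
  agg <- function(m) {
    out <- matrix(0, n_m, 4L, dimnames = list(who, zones$labels))
    for (z in 1:4) {
      rows <- zi == z
      if (any(rows)) out[, z] <- colSums(m[rows, , drop = FALSE])
    }
    out
  }
  w <- agg(seg)
  structure(list(work = w,
                 positive = agg(pmax(seg, 0)),
                 negative = agg(pmin(seg, 0)),
                 total = rowSums(w),
                 zones = zones),
            class = "muscle_work_report")
}

#' @export
print.muscle_work_report <- function(x, ...) {
  cat("Net muscle work per propulsion zone (J):\n")
  print(round(cbind(x$work, cycle = x$total), 4L))
  invisible(x)
}

#' Joint range-of-motion summary
#'
#' Extrema of the modeled joint angles over the evaluation cycle, with flags
#' for excursions beyond configured ergonomic ranges.
#'
#' @param trace a \code{\link{simulate_cycles}} trace.
#' @param ergonomic_deg optional named list of \code{c(min, max)} ranges in
#'   degrees per joint (\code{shoulder}, \code{elbow}); defaults to the arm
#'   configuration's joint ranges.
#' @return Data frame with columns \code{joint}, \code{min_deg},
#'   \code{max_deg}, \code{range_deg}, \code{exceeds}.
#' @export
rom_summary <- function(trace, ergonomic_deg = NULL) {
  cyc <- if (trace$n_cycles == 1L) trace else trace_cycle(trace)
  if (is.null(ergonomic_deg))
    ergonomic_deg <- list(shoulder = trace$arm$shoulder_range * 180 / pi,
                          elbow = trace$arm$elbow_range * 180 / pi)
  ang <- cbind(shoulder = cyc$q[, 1L] * 180 / pi,
               elbow = cyc$flexion_deg)
  out <- data.frame(joint = colnames(ang),
                    min_deg = apply(ang, 2L, min),
                    max_deg = apply(ang, 2L, max),
                    row.names = NULL)
  out$range_deg <- out$max_deg - out$min_deg
  out$exceeds <- vapply(seq_len(nrow(out)), function(i) {
    erg <- ergonomic_deg[[out$joint[i]]]
    out$min_deg[i] < erg[1L] - 1e-9 || out$max_deg[i] > erg[2L] + 1e-9
  }, logical(1L))
  out
}

#' Normalized fiber mechanics
#'
#' Per-muscle normalized fiber length and velocity over the evaluation
#' cycle, with the activity mask at the conventional 20 percent activation
#' threshold used when judging whether muscles operate near their optimal
#' fiber length while active.
#'
#' @param trace a \code{\link{simulate_cycles}} trace.
#' @param threshold activation level defining "active" (default 0.2).
#' @return List: \code{time}, \code{lnorm} (fiber length / optimal length),
#'   \code{vnorm} (fiber velocity / maximum shortening velocity, shortening
#'   negative), \code{active} (logical mask a > threshold).
#' @export
fiber_mechanics <- function(trace, threshold = 0.2) {
  cyc <- if (trace$n_cycles == 1L) trace else trace_cycle(trace)
  vrel <- sweep(cyc$vnorm, 2L, trace$muscles$v_max, "/")
  colnames(vrel) <- colnames(cyc$lnorm) <- trace$muscles$name
  list(time = cyc$time, lnorm = cyc$lnorm, vnorm = vrel,
       active = cyc$a > threshold)
}

#' Peak muscle forces
#'
#' @param trace a \code{\link{simulate_cycles}} trace.
#' @return Named vector of per-muscle maximum tendon force (N) over the
#'   evaluation cycle.
#' @export
peak_forces <- function(trace) {
  cyc <- if (trace$n_cycles == 1L) trace else trace_cycle(trace)
  stats::setNames(apply(cyc$force, 2L, max), trace$muscles$name)
}

#' Write a simulation trace as CSV
#'
#' One row per output sample of the whole trace: time, crank angle, joint
#' angles, per-muscle activation and force, crank torque and power.
#'
#' @param trace a \code{\link{simulate_cycles}} trace.
#' @param path output file.
#' @return The output path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  who <- trace$muscles$name
  df <- data.frame(time_s = trace$time, theta_rad = trace$theta,
                   q_shoulder_rad = trace$q[, 1L],
                   q_elbow_rad = trace$q[, 2L], check.names = FALSE)
  a <- as.data.frame(trace$a)
  names(a) <- paste0("a_", who)
  f <- as.data.frame(trace$force)
  names(f) <- paste0("F_", who, "_N")
  df <- cbind(df, a, f,
              tau_crank_Nm = trace$tau_crank, power_W = trace$power)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a result bundle
#'
#' Writes a deterministic JSON summary (shape parameters in metres and
#' degrees, circularity, net power, penalties, per-zone muscle work, joint
#' ranges of motion, peak forces) plus CSV tables for the trace and the
#' muscle-work matrix.
#'
#' @param trace a \code{\link{simulate_cycles}} trace.
#' @param shape the \code{\link{path_shape}} that generated it.
#' @param dir output directory (created if needed).
#' @param fit optional \code{\link{optimize_propulsion}} result to include
#'   (objective, penalties, history length).
#' @param zones a \code{\link{zone_partition}}.
#' @return Invisibly, the summary list.
#' @export
propulsion_report <- function(trace, shape, dir, fit = NULL,
                              zones = zone_partition()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  poly <- sample_path(shape, 720L)
  mw <- muscle_work(trace, zones)
  rom <- rom_summary(trace)
  summary <- list(
    shape = list(A_m = shape$A, B_m = shape$B, n = shape$n,
                 beta_deg = shape$beta * 180 / pi),
    circularity = circularity(poly),
    net_power_W = net_propulsion_power(trace),
    omega_rpm = trace$mech$omega_rpm,
    muscle_work_J = as.data.frame(cbind(mw$work, cycle = mw$total)),
    rom_deg = rom,
    peak_forces_N = as.list(peak_forces(trace)))
  if (!is.null(fit))
    summary$optimization <- list(objective = fit$report$total,
                                 penalties = fit$report$penalties,
                                 n_eval = fit$n_eval,
                                 n_accepted = nrow(fit$history),
                                 seed = fit$seed)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_trace_csv(trace, file.path(dir, "trace.csv"))
  utils::write.csv(data.frame(muscle = rownames(mw$work), mw$work,
                              cycle = mw$total, row.names = NULL),
                   file.path(dir, "muscle_work.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(summary)
}
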