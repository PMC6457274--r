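# Shared fixtures: the optimized shape reported for handle-based propulsion,
# small muscle rosters and a synthetic-trace builder for analysis unit tests.

printed_shape <- function(beta_deg = 15.95) {
  path_shape(0.151, 0.152, 0.7, beta_deg = beta_deg)
}

printed_profile <- function(n = 720L, beta_deg = 15.95) {
  to_crank_length_profile(sample_path(printed_shape(beta_deg), n))
}

four_muscle_set <- function() {
  tab <- as.data.frame(default_muscles())
  muscle_set(tab[tab$name %in% c("Delt1", "Delt3", "BicLong", "TriLong"), ])
}

pair_muscle_set <- function() {
  tab <- as.data.frame(default_muscles())
  muscle_set(tab[tab$name %in% c("Delt1", "Delt3"), ])
}

# Hand-built single-cycle trace with prescribed muscle force and
# musculotendon velocity histories; kinematic fields are filled with
# consistent placeholders so the analysis operations can run on exactly
# known inputs.
synthetic_trace <- function(force, v_mt, a = NULL, muscles = NULL,
                            omega_rpm = 50, q = NULL, flexion_deg = NULL) {
  n <- nrow(force)
  n_m <- ncol(force)
  mech <- mechanism_config(omega_rpm = omega_rpm)
  period <- 2 * pi / mech$omega
  time <- seq(0, period, length.out = n)
  if (is.null(muscles)) {
    tab <- as.data.frame(default_muscles())[seq_len(n_m), ]
    muscles <- muscle_set(tab)
  }
  if (is.null(a)) a <- matrix(0, n, n_m)
  if (is.null(q)) q <- matrix(0, n, 2L)
  if (is.null(flexion_deg)) flexion_deg <- rep(90, n)
  cosa <- cos(muscles$penn_deg * pi / 180)
  lnorm <- matrix(1, n, n_m)
  structure(list(time = time, theta = mech$omega * time %% (2 * pi),
                 cycle = rep(1L, n), q = q, qd = matrix(0, n, 2L),
                 flexion_deg = flexion_deg, a = a, force = force,
                 l_mt = sweep(lnorm, 2L, muscles$L_opt_m * cosa, "*") +
                   matrix(muscles$L_slack_m, n, n_m, byrow = TRUE),
                 v_mt = v_mt, lnorm = lnorm,
                 vnorm = sweep(sweep(v_mt, 2L, cosa, "/"), 2L,
                               muscles$L_opt_m, "/"),
                 tau_muscle = matrix(0, n, 2L),
                 tau_limit = matrix(0, n, 2L), tau_id = matrix(0, n, 2L),
                 tau_crank = rep(0, n), power = rep(0, n),
                 range_excursion = matrix(0, n, 2L),
                 period = period, n_out = n - 1L, n_cycles = 1L,
                 eval_cycle = 1L, branch = 1,
                 muscles = muscles, arm = arm_config(), mech = mech),
            class = "propulsion_trace")
}

# closed polyline through explicit polar vertices (for degenerate-geometry
# error paths that the parametric family itself does not produce)
polar_polyline <- function(angles_deg, radii) {
  a <- angles_deg * pi / 180
  xy <- cbind(radii * cos(a), radii * sin(a))
  xy <- rbind(xy, xy[1L, ])
  structure(list(theta = c(a, a[1L]), xy = xy,
                 star_shaped = hbpsim:::.is_star_shaped(xy)),
            class = "path_polyline")
}
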