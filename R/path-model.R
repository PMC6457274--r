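#' Parametric handle-path shape
#'
#' Constructs the four-parameter closed handle path used for propulsion-shape
#' optimization. In the crank frame (origin at the crank centre) the untilted
#' path is
#' \deqn{P_x(\theta) = A \cos\theta, \qquad
#'       P_y(\theta) = B \sin\theta \, \sin^n(\theta/2),}
#' and the full path is the untilted curve rotated clockwise by the tilt
#' angle \eqn{\beta}. With \code{n = 0} and \code{A = B} the path degenerates
#' to a circle of radius \code{A}; increasing \code{n} flattens one side of
#' the curve, producing the egg-like profiles typical of optimized propulsion
#' strokes.
#'
#' @param A,B scale factors (m). Both are bounded by the slider travel of the
#'   crank, \code{[0.030, 0.155]} m, so that the path stays realizable by the
#'   mechanism.
#' @param n shape exponent, dimensionless, in \code{[0, 1]}.
#' @param beta_deg tilt angle in degrees; positive tilts the path clockwise
#'   about the crank centre. Stored internally in radians.
#' @return An object of class \code{"path_shape"} with fields \code{A},
#'   \code{B}, \code{n} and \code{beta} (radians).
#' @examples
#' shp <- path_shape(0.151, 0.152, 0.7, beta_deg = 15.95)
#' eval_path(shp, c(0, pi / 2, pi))
#' @export
path_shape <- function(A, B, n, beta_deg = 0) {
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(n), is.numeric(beta_deg),
            length(A) == 1L, length(B) == 1L, length(n) == 1L,
            length(beta_deg) == 1L)
  if (!is.finite(A) || A < 0.030 || A > 0.155)
    stop("'A' must lie in [0.030, 0.155] m (slider travel), got ", A)
  if (!is.finite(B) || B < 0.030 || B > 0.155)
    stop("'B' must lie in [0.030, 0.155] m (slider travel), got ", B)
  if (!is.finite(n) || n < 0 || n > 1)
    stop("shape exponent 'n' must lie in [0, 1], got ", n)
  if (!is.finite(beta_deg)) stop("'beta_deg' must be finite")
  structure(list(A = A, B = B, n = n, beta = beta_deg * pi / 180),
            class = "path_shape")
}

#' @export
print.path_shape <- function(x, ...) {
  cat(sprintf("Handle path shape: A = %.4f m, B = %.4f m, n = %.3f, beta = %.2f deg\n",
              x$A, x$B, x$n, x$beta * 180 / pi))
  invisible(x)
}

#' Evaluate the handle path at given path angles
#'
#' @param shape a \code{\link{path_shape}}.
#' @param theta path angle(s) in radians, in \code{[0, 2*pi]}.
#' @return An n-by-2 matrix of (x, y) coordinates in metres, crank frame.
#' @export
eval_path <- function(shape, theta) {
  stopifnot(inherits(shape, "path_shape"), is.numeric(theta))
  if (any(theta < -1e-12 | theta > 2 * pi + 1e-12))
    stop("'theta' must lie in [0, 2*pi]")
  # sin(theta/2) >= 0 on [0, 2*pi], so the fractional power is well defined
  px <- shape$A * cos(theta)
  py <- shape$B * sin(theta) * sin(theta / 2)^shape$n
  cb <- cos(shape$beta)
  sb <- sin(shape$beta)
  # clockwise (negative mathematical sense) rotation by beta
  cbind(x = cb * px + sb * py, y = -sb * px + cb * py)
}

#' Sample the handle path into a closed polyline
#'
#' Evaluates the path on a uniform angle grid over one revolution and checks
#' whether the result is star-shaped about the crank centre (polar angle
#' strictly monotonic along the curve), which is required for the conversion
#' to an effective-crank-length profile.
#'
#' @param shape a \code{\link{path_shape}}.
#' @param n_points number of grid points including the duplicated closure
#'   point (at least 16).
#' @return An object of class \code{"path_polyline"}: list with \code{theta}
#'   (the generating grid), \code{xy} (n-by-2 matrix, first row equals the
#'   last), and \code{star_shaped} (logical flag).
#' @export
sample_path <- function(shape, n_points = 720L) {
  stopifnot(inherits(shape, "path_shape"))
  n_points <- as.integer(n_points)
  if (n_points < 16L) stop("'n_points' must be at least 16")
  theta <- seq(0, 2 * pi, length.out = n_points)
  xy <- eval_path(shape, theta)
  xy[n_points, ] <- xy[1L, ]  # exact closure (theta = 2*pi aliases theta = 0)
  structure(list(theta = theta, xy = xy,
                 star_shaped = .is_star_shaped(xy)),
            class = "path_polyline")
}

# Polar angle strictly monotonic (mod 2*pi) along the open polyline,
# in either sense, and the origin strictly inside (all radii positive).
.is_star_shaped <- function(xy) {
  m <- nrow(xy) - 1L                      # drop duplicated closure point
  x <- xy[seq_len(m), 1L]
  y <- xy[seq_len(m), 2L]
  if (any(x^2 + y^2 < 1e-16)) return(FALSE)
  phi <- atan2(y, x)
  d <- diff(c(phi, phi[1L]))
  d <- (d + pi) %% (2 * pi) - pi          # wrap steps to (-pi, pi]
  total <- sum(d)
  if (abs(abs(total) - 2 * pi) > 1e-6) return(FALSE)  # winds exactly once
  all(d > 0) || all(d < 0)
}

# Naive O(n^2) proper-crossing test; only consulted for non-star polylines,
# since a polyline star-shaped about an interior point cannot self-intersect.
.self_intersects <- function(xy) {
  n <- nrow(xy) - 1L
  p <- xy[seq_len(n), , drop = FALSE]
  q <- xy[c(seq(2L, n), 1L), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    js <- seq(i + 2L, n)
    js <- js[!(i == 1L & js == n)]        # skip segments sharing an endpoint
    if (!length(js)) next
    d1 <- cross(p[i, 1], p[i, 2], q[i, 1], q[i, 2], p[js, 1], p[js, 2])
    d2 <- cross(p[i, 1], p[i, 2], q[i, 1], q[i, 2], q[js, 1], q[js, 2])
    d3 <- cross(p[js, 1], p[js, 2], q[js, 1], q[js, 2], p[i, 1], p[i, 2])
    d4 <- cross(p[js, 1], p[js, 2], q[js, 1], q[js, 2], q[i, 1], q[i, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Circularity ratio of a closed path
#'
#' Computes the isoperimetric (Miller) compactness ratio
#' \eqn{4\pi \cdot \mathrm{Area} / \mathrm{Perimeter}^2}: 1 for a circle,
#' smaller for any other shape. Area is computed by the shoelace formula and
#' the perimeter as the chord-length sum over the polyline.
#'
#' @param poly a \code{\link{sample_path}} polyline (closed,
#'   non-self-intersecting).
#' @return Circularity in (0, 1].
#' @export
circularity <- function(poly) {
  stopifnot(inherits(poly, "path_polyline"))
  xy <- poly$xy
  if (max(abs(xy[1L, ] - xy[nrow(xy), ])) > 1e-9)
    stop("polyline is not closed")
  if (!poly$star_shaped && .self_intersects(xy))
    stop("polyline is self-intersecting; circularity is undefined")
  x <- xy[, 1L]
  y <- xy[, 2L]
  m <- nrow(xy)
  area <- abs(sum(x[-m] * y[-1L] - x[-1L] * y[-m]) / 2)
  perim <- sum(sqrt(diff(x)^2 + diff(y)^2))
  4 * pi * area / perim^2
}

#' Effective-crank-length profile of a handle path
#'
#' Converts a star-shaped handle path to polar form about the crank centre and
#' tabulates the effective crank length \eqn{C_L} as a single-valued function
#' of the crank angle, resampled by linear interpolation onto a uniform
#' periodic grid. This is the prescribed slider motion that realizes the path
#' on the crank-slider mechanism.
#'
#' The crank angle is measured in the crank's rotation sense from the positive
#' x axis of the crank frame, so the profile is independent of how the path
#' was parameterized.
#'
#' @param poly a star-shaped \code{\link{sample_path}} polyline.
#' @param sense rotation sense of the crank, \code{"cw"} (default, propulsion
#'   convention) or \code{"ccw"}.
#' @param n_grid number of uniform crank-angle grid points over one turn.
#' @param bounds slider travel limits (m); violations raise an error naming
#'   the offending crank angle unless \code{check_bounds = FALSE}.
#' @param check_bounds logical; disable to obtain out-of-bound profiles for
#'   penalty evaluation.
#' @return Object of class \code{"crank_length_profile"}: list with
#'   \code{phi} (grid, radians in \code{[0, 2*pi)}), \code{CL} (m),
#'   \code{sense} and \code{bounds}.
#' @export
to_crank_length_profile <- function(poly, sense = c("cw", "ccw"),
                                    n_grid = 720L,
                                    bounds = c(0.030, 0.155),
                                    check_bounds = TRUE) {
  stopifnot(inherits(poly, "path_polyline"))
  sense <- match.arg(sense)
  if (!poly$star_shaped)
    stop("path is not star-shaped about the crank centre: ",
         "the effective crank length would be multivalued")
  m <- nrow(poly$xy) - 1L
  x <- poly$xy[seq_len(m), 1L]
  y <- poly$xy[seq_len(m), 2L]
  r <- sqrt(x^2 + y^2)
  phi <- atan2(y, x)
  if (sense == "cw") phi <- -phi
  phi <- phi %% (2 * pi)
  ord <- order(phi)
  phi <- phi[ord]
  r <- r[ord]
  # periodic extension for linear interpolation across the wrap point
  phi_ext <- c(phi[m] - 2 * pi, phi, phi[1L] + 2 * pi)
  r_ext <- c(r[m], r, r[1L])
  grid <- seq(0, 2 * pi, length.out = n_grid + 1L)[seq_len(n_grid)]
  cl <- stats::approx(phi_ext, r_ext, xout = grid, method = "linear")$y
  if (check_bounds) {
    bad <- which(cl < bounds[1L] | cl > bounds[2L])
    if (length(bad))
      stop(sprintf(
        "effective crank length %.4f m at crank angle %.3f rad violates bounds [%.3f, %.3f] m",
        cl[bad[1L]], grid[bad[1L]], bounds[1L], bounds[2L]))
  }
  structure(list(phi = grid, CL = cl, sense = sense, bounds = bounds),
            class = "crank_length_profile")
}

#' Evaluate a crank-length profile at arbitrary crank angles
#'
#' @param profile a \code{\link{to_crank_length_profile}} object.
#' @param phi crank angle(s) in radians (any value; wrapped periodically).
#' @param deriv 0 for the length (m) or 1 for its derivative with respect to
#'   crank angle (m/rad), from central differences of the tabulated profile.
#' @return Numeric vector.
#' @export
profile_eval <- function(profile, phi, deriv = 0L) {
  stopifnot(inherits(profile, "crank_length_profile"))
  n <- length(profile$phi)
  h <- 2 * pi / n
  phi <- phi %% (2 * pi)
  if (deriv == 0L) {
    vals <- profile$CL
  } else if (deriv == 1L) {
    vals <- (profile$CL[c(seq(2L, n), 1L)] - profile$CL[c(n, seq_len(n - 1L))]) / (2 * h)
  } else stop("'deriv' must be 0 or 1")
  g_ext <- c(profile$phi, 2 * pi)
  v_ext <- c(vals, vals[1L])
  stats::approx(g_ext, v_ext, xout = phi, method = "linear")$y
}
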