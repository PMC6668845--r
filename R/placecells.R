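#' Uniform grid of Gaussian place fields
#'
#' Models a population of hippocampal place cells as `n_x` x `n_y` Gaussian
#' tuning surfaces with centers evenly spaced over a rectangular extent
#' (default 2 x 2 m, mimicking dorsal hippocampus coverage of the enclosure).
#' Cell `k` responds to a location `s` with mean firing rate
#' \deqn{f_k(s) = \exp(-\|s - c_k\|^2 / w_k), \quad w_k = r_k^2 / (-\log\Theta),}
#' so the activation equals the radius threshold `theta` exactly at distance
#' `r` from the center: the bulk of the response is contained in a circle of
#' radius `r`.
#'
#' @param n_x,n_y Grid dimensions (default 16 x 16, i.e. K = 256 cells).
#' @param extent Rectangle `c(xmin, xmax, ymin, ymax)` covered by the grid.
#'   Default `c(-1, 1, -1, 1)` (a 2 x 2 m enclosure centered on the origin).
#' @param r Place-field radius in meters, shared by all cells. Defaults to
#'   the grid spacing.
#' @param theta Radius threshold in (0, 1): the activation at distance `r`.
#'   Default 0.2.
#' @return An object of class `place_grid` with elements `centers` (K x 2),
#'   `r`, `theta`, `w`, `n_x`, `n_y`, `extent`, `K`.
#' @examples
#' g <- make_grid()
#' g$K          # 256
#' @export
make_grid <- function(n_x = 16, n_y = 16, extent = c(-1, 1, -1, 1),
                      r = NULL, theta = 0.2) {
  stopifnot(n_x >= 1, n_y >= 1)
  if (theta <= 0 || theta >= 1)
    stop("theta must lie strictly between 0 and 1")
  sx <- (extent[2] - extent[1]) / n_x
  sy <- (extent[4] - extent[3]) / n_y
  if (is.null(r)) r <- sx
  if (r <= 0) stop("place-field radius must be positive")
  cx <- extent[1] + sx * (seq_len(n_x) - 0.5)
  cy <- extent[3] + sy * (seq_len(n_y) - 0.5)
  centers <- as.matrix(expand.grid(x = cx, y = cy))
  dimnames(centers) <- NULL
  structure(list(centers = centers, r = r, theta = theta,
                 w = r^2 / (-log(theta)), n_x = n_x, n_y = n_y,
                 extent = extent, K = n_x * n_y),
            class = "place_grid")
}

#' @export
print.place_grid <- function(x, ...) {
  cat(sprintf("<place_grid> %d x %d fields over [%.2f, %.2f] x [%.2f, %.2f] m, r = %.3f m, theta = %.2f\n",
              x$n_x, x$n_y, x$extent[1], x$extent[2], x$extent[3],
              x$extent[4], x$r, x$theta))
  invisible(x)
}

#' Place-cell activation pattern of a single location
#'
#' Projects a 2D location through the K radial basis functions of the grid.
#' Every component lies in (0, 1]; locations outside the grid extent are
#' encoded too, just weakly.
#'
#' @param s Numeric length-2 location (x, y) in meters.
#' @param grid A [make_grid()] object.
#' @return Numeric vector of K mean firing rates.
#' @examples
#' g <- make_grid()
#' max(encode_point(g$centers[1, ], g))  # 1 at a field center
#' @export
encode_point <- function(s, grid) {
  d2 <- (s[1] - grid$centers[, 1])^2 + (s[2] - grid$centers[, 2])^2
  exp(-d2 / grid$w)
}

#' Place-cell activation raster of a trajectory
#'
#' Applies [encode_point()] to every sample of a trajectory.
#'
#' @param traj A [trajectory()] or an n x 2 point matrix.
#' @param grid A [make_grid()] object.
#' @return An n x K matrix (rows = time, columns = cells) of class
#'   `activation_raster`.
#' @export
encode_trajectory <- function(traj, grid) {
  pts <- if (inherits(traj, "trajectory")) traj$points else as.matrix(traj)
  out <- cpp_encode(pts, grid$centers, grid$w)
  class(out) <- c("activation_raster", class(out))
  out
}

#' Motion constraint of the simulated animal
#'
#' The agent's moves are restricted to a circle of radius `max_step` around
#' its current location (default 10 cm) and to headings within
#' `heading_cone` degrees left and right of straight ahead (default 110).
#' The reachable set is realized as a deterministic polar lattice of
#' `n_radii` radii times `n_angles` angles, which makes the decoder's argmax
#' reproducible.
#'
#' @param max_step Maximum displacement per step in meters.
#' @param heading_cone Half-opening of the heading cone in degrees, in
#'   (0, 180].
#' @param n_radii,n_angles Resolution of the candidate lattice.
#' @return An object of class `motion_constraint`.
#' @export
motion_constraint <- function(max_step = 0.10, heading_cone = 110,
                              n_radii = 8, n_angles = 23) {
  stopifnot(max_step > 0, heading_cone > 0, heading_cone <= 180,
            n_radii >= 1, n_angles >= 2)
  structure(list(max_step = max_step, heading_cone = heading_cone,
                 n_radii = n_radii, n_angles = n_angles),
            class = "motion_constraint")
}

#' Candidate next locations under a motion constraint
#'
#' @param s Current location (x, y).
#' @param heading Current heading in radians, or `NA` when undefined (e.g.
#'   at the first step), in which case the full circle is searched.
#' @param mc A [motion_constraint()].
#' @return An m x 2 matrix of candidate locations: the current location
#'   first (staying put is reachable, which makes the decoder idempotent on
#'   noiseless self-codes), then the polar lattice with the radius index
#'   varying fastest.
#' @export
candidate_lattice <- function(s, heading, mc = motion_constraint()) {
  cone <- mc$heading_cone * pi / 180
  ang <- if (is.na(heading)) seq(-pi, pi, length.out = mc$n_angles)
         else seq(heading - cone, heading + cone, length.out = mc$n_angles)
  rad <- seq(mc$max_step / mc$n_radii, mc$max_step, length.out = mc$n_radii)
  g <- expand.grid(r = rad, a = ang)
  rbind(c(s[1], s[2]),
        cbind(s[1] + g$r * cos(g$a), s[2] + g$r * sin(g$a)))
}

#' Bayesian spatial filter: decode a predicted activation pattern
#'
#' Converts a (possibly noisy) predicted place-cell activation pattern `eta`
#' into the most probable *reachable* next location: the candidate `q` in
#' the motion-constrained lattice that maximizes a match score between `eta`
#' and the noise-free code `encode_point(q)`, plus an optional uniform
#' score perturbation `u ~ U(0, noise_m)` per candidate. The perturbation
#' breaks degenerate ties (e.g. an all-zero prediction) and, during random
#' walks, biases generation towards unexplored branches.
#'
#' The match score is the negative mean squared difference between `eta` and
#' the candidate's code; exact ties resolve to the lowest candidate index.
#'
#' @param eta Numeric K-vector, the predicted activation pattern.
#' @param s_now Current location (x, y).
#' @param heading Current heading in radians (`NA` = undefined, search the
#'   full circle).
#' @param grid A [make_grid()] object.
#' @param mc A [motion_constraint()].
#' @param noise_m Upper bound of the uniform score noise (0 disables it).
#' @return The chosen next location as a length-2 numeric vector.
#' @examples
#' g <- make_grid()
#' q <- c(0.05, 0)
#' spatial_filter(encode_point(q, g), c(0, 0), heading = 0, g)
#' @export
spatial_filter <- function(eta, s_now, heading, grid,
                           mc = motion_constraint(), noise_m = 0) {
  if (length(eta) != grid$K)
    stop("eta must have one component per place cell")
  cand <- candidate_lattice(s_now, heading, mc)
  if (!nrow(cand)) stop("empty reachable set")
  fc <- cpp_encode(cand, grid$centers, grid$w)
  sc <- -rowMeans((fc - matrix(eta, nrow(cand), grid$K, byrow = TRUE))^2)
  if (noise_m > 0) sc <- sc + stats::runif(length(sc), 0, noise_m)
  cand[which.max(sc), ]
}
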