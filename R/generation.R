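#' Sequence generation configuration
#'
#' @param prime_steps Number of teacher-forced priming steps `p` (default
#'   10, the snippet length: the network never saw longer context during
#'   training).
#' @param max_steps Total trajectory length in samples, priming included.
#'   `NULL` (default) lets the caller derive it from a target sequence.
#' @param mode `"autonomous"` (closed loop through the spatial filter) or
#'   `"non_autonomous"` (teacher forced).
#' @param noise_m Uniform score-noise bound passed to the spatial filter.
#'   Default 0; random-walk evaluations typically use a small positive
#'   value (about 1% of the typical candidate score spread) to explore
#'   alternative branches.
#' @param mc A [motion_constraint()].
#' @param histogram_bins Bins per axis for [trajectory_histogram()].
#' @return An object of class `generation_config`.
#' @export
generation_config <- function(prime_steps = 10, max_steps = NULL,
                              mode = c("autonomous", "non_autonomous"),
                              noise_m = 0, mc = motion_constraint(),
                              histogram_bins = c(50, 50)) {
  mode <- match.arg(mode)
  stopifnot(prime_steps >= 1)
  if (!is.null(max_steps) && max_steps < prime_steps)
    stop("max_steps cannot be smaller than prime_steps")
  structure(list(prime_steps = prime_steps, max_steps = max_steps,
                 mode = mode, noise_m = noise_m, mc = mc,
                 histogram_bins = histogram_bins),
            class = "generation_config")
}

#' Autonomous (closed-loop) trajectory generation
#'
#' The reservoir is teacher-forced with the first `prime_steps` points of
#' the prime, then runs in closed loop: the readout's prediction of the
#' next place-cell pattern is decoded by the spatial filter to the most
#' probable reachable location, the agent moves there, and the clean code
#' of the reached location is injected as the next input. The heading
#' constraint follows the last displacement (the prime's, during priming).
#'
#' @param net A trained [init_network()] reservoir.
#' @param grid The [make_grid()] used for training.
#' @param prime An n x 2 matrix or [trajectory()] whose first
#'   `prime_steps` points prime the network.
#' @param cfg A [generation_config()]; `max_steps` must be set.
#' @return A [trajectory()] of `max_steps` points (prime included), with
#'   attribute `prime_steps`.
#' @export
autonomous_generate <- function(net, grid, prime,
                                cfg = generation_config()) {
  pts <- if (inherits(prime, "trajectory")) prime$points else as.matrix(prime)
  p <- cfg$prime_steps
  if (nrow(pts) < p) stop("prime shorter than prime_steps")
  if (is.null(cfg$max_steps)) stop("cfg$max_steps must be set")
  n_gen <- cfg$max_steps - p
  if (n_gen < 0) stop("max_steps must be at least prime_steps")
  par <- net$params
  cone <- cfg$mc$heading_cone * pi / 180
  out <- cpp_autonomous(net$w_ffwd, net$w_rec, net$w_ro, grid$centers,
                        grid$w, pts[seq_len(p), , drop = FALSE],
                        n_gen, par$leak_rate, par$theta_res, par$theta_ro,
                        par$reset_amplitude, cfg$mc$max_step, cone,
                        cfg$mc$n_radii, cfg$mc$n_angles, cfg$noise_m)
  tr <- trajectory(out, resolution = 1 / cfg$mc$max_step)
  attr(tr, "prime_steps") <- p
  tr
}

#' Non-autonomous (teacher-forced) evaluation
#'
#' Drives the reservoir with the target's own activation codes at every
#' step, decodes each next-step prediction through the spatial filter from
#' the *expected* current position, and reports the Euclidean distance
#' between the decoded prediction and the true next point. This evaluates
#' pure next-step prediction, preventing error amplification: small
#' prediction errors show up as a zigzag of per-step spatial errors rather
#' than as a diverging path.
#'
#' @param net A trained [init_network()] reservoir.
#' @param grid The [make_grid()] used for training.
#' @param target A [trajectory()] (or n x 2 matrix) to follow.
#' @param cfg A [generation_config()].
#' @return A list with `predicted` ((n-1) x 2 decoded next locations) and
#'   `error` (length n-1 per-step spatial error in meters).
#' @export
non_autonomous_generate <- function(net, grid, target,
                                    cfg = generation_config()) {
  pts <- if (inherits(target, "trajectory")) target$points
         else as.matrix(target)
  n <- nrow(pts)
  if (n < 2) stop("target needs at least 2 points")
  ras <- encode_trajectory(pts, grid)
  run <- drive_reservoir(net, ras)
  pred <- matrix(NA_real_, n - 1, 2)
  err <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    heading <- if (i == 1) NA_real_
               else atan2(pts[i, 2] - pts[i - 1, 2],
                          pts[i, 1] - pts[i - 1, 1])
    pred[i, ] <- spatial_filter(run$x_ro[i, ], pts[i, ], heading, grid,
                                cfg$mc, cfg$noise_m)
    err[i] <- sqrt(sum((pred[i, ] - pts[i + 1, ])^2))
  }
  list(predicted = pred, error = err)
}

#' Random-walk population evaluation
#'
#' Evaluates a population of trained models by running each several times
#' in autonomous mode with independent spatial-filter noise, as in the
#' stencil-buffer histogram evaluations (the full-scale setting runs 1000
#' model copies 10 times each).
#'
#' @param nets List of trained reservoirs.
#' @param grid The [make_grid()] used for training.
#' @param prime Priming trajectory or point matrix.
#' @param cfg A [generation_config()] with `max_steps` set and typically
#'   `noise_m > 0`.
#' @param runs_per_net Autonomous generations per network.
#' @return A list of [trajectory()] objects of length
#'   `length(nets) * runs_per_net`, with attribute `net_id`.
#' @export
random_walk <- function(nets, grid, prime, cfg, runs_per_net = 10) {
  stopifnot(length(nets) >= 1, runs_per_net >= 1)
  out <- vector("list", length(nets) * runs_per_net)
  ids <- integer(length(out))
  k <- 0L
  for (i in seq_along(nets)) {
    for (r in seq_len(runs_per_net)) {
      k <- k + 1L
      out[[k]] <- autonomous_generate(nets[[i]], grid, prime, cfg)
      ids[k] <- i
    }
  }
  attr(out, "net_id") <- ids
  out
}

#' Two-dimensional trajectory histogram
#'
#' Superimposes a batch of trajectories on a 2D bin grid covering the
#' arena and counts samples per bin (the "stencil buffer" view of where
#' generated behavior concentrates). Points outside the arena bounding box
#' are clipped to the boundary bin and still counted.
#'
#' @param trajs List of trajectories (or n x 2 matrices).
#' @param arena An [arena_config()] fixing the covered extent.
#' @param bins Bins per axis, `c(nx, ny)`.
#' @param include_prime Include priming samples of generated trajectories
#'   (default FALSE).
#' @return An object of class `trajectory_histogram`: list with `counts`
#'   (nx x ny matrix), `xbreaks`, `ybreaks`, `n_trajectories`, `n_points`.
#' @export
trajectory_histogram <- function(trajs, arena, bins = c(50, 50),
                                 include_prime = FALSE) {
  stopifnot(all(bins >= 1))
  if (arena$shape == "circular") {
    xlim <- c(-arena$radius_m, arena$radius_m)
    ylim <- xlim
  } else {
    xlim <- c(-arena$extent_m[1] / 2, arena$extent_m[1] / 2)
    ylim <- c(-arena$extent_m[2] / 2, arena$extent_m[2] / 2)
  }
  xbreaks <- seq(xlim[1], xlim[2], length.out = bins[1] + 1)
  ybreaks <- seq(ylim[1], ylim[2], length.out = bins[2] + 1)
  counts <- matrix(0L, bins[1], bins[2])
  n_points <- 0L
  n_clipped <- 0L
  for (tr in trajs) {
    pts <- if (inherits(tr, "trajectory")) tr$points else as.matrix(tr)
    if (!include_prime && !is.null(attr(tr, "prime_steps"))) {
      p <- attr(tr, "prime_steps")
      if (nrow(pts) > p) pts <- pts[-seq_len(p), , drop = FALSE]
    }
    ix <- findInterval(pts[, 1], xbreaks, rightmost.closed = TRUE)
    iy <- findInterval(pts[, 2], ybreaks, rightmost.closed = TRUE)
    n_clipped <- n_clipped + sum(ix < 1 | ix > bins[1] |
                                   iy < 1 | iy > bins[2])
    ix <- pmin(pmax(ix, 1L), bins[1])
    iy <- pmin(pmax(iy, 1L), bins[2])
    for (j in seq_len(nrow(pts)))
      counts[ix[j], iy[j]] <- counts[ix[j], iy[j]] + 1L
    n_points <- n_points + nrow(pts)
  }
  if (n_clipped > 0)
    message(n_clipped, " point(s) outside the arena clipped to boundary bins")
  structure(list(counts = counts, xbreaks = xbreaks, ybreaks = ybreaks,
                 n_trajectories = length(trajs), n_points = n_points),
            class = "trajectory_histogram")
}

#' @describeIn trajectory_histogram Render the histogram as an image map
#'   (log1p color scale).
#' @param x A `trajectory_histogram`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.trajectory_histogram <- function(x, ...) {
  graphics::image(x$xbreaks, x$ybreaks, log1p(x$counts),
                  xlab = "x (m)", ylab = "y (m)", useRaster = TRUE, ...)
  invisible(x)
}

#' @export
print.trajectory_histogram <- function(x, ...) {
  cat(sprintf("<trajectory_histogram> %d x %d bins, %d trajectories, %d points\n",
              nrow(x$counts), ncol(x$counts), x$n_trajectories, x$n_points))
  invisible(x)
}
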