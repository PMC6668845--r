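#' Arena configuration
#'
#' Describes the physical enclosure the simulated animal navigates: either a
#' circular open-field arena (the multi-feeder foraging task uses a circle of
#' radius 1.51 m) or a rectangular enclosure (the place-field model assumes a
#' closed 2 x 2 m space). Feeders are point locations inside the arena; a
#' baited feeder delivers a reward of the given magnitude when visited.
#'
#' @param shape `"circular"` or `"rectangular"`.
#' @param radius_m Arena radius in meters (circular arenas). Default 1.51.
#' @param extent_m Width and height in meters (rectangular arenas).
#'   Default `c(2, 2)`.
#' @param feeders A data frame with columns `label`, `x`, `y`, `baited`,
#'   `reward_magnitude`, as built by [feeder()]. May be empty.
#' @return An object of class `arena`.
#' @examples
#' arena_config("circular", radius_m = 1.51,
#'              feeders = feeder("A", 0.5, 0.5, baited = TRUE))
#' @export
arena_config <- function(shape = c("circular", "rectangular"),
                         radius_m = 1.51, extent_m = c(2, 2),
                         feeders = empty_feeders()) {
  shape <- match.arg(shape)
  feeders <- as.data.frame(feeders)
  stopifnot(all(c("label", "x", "y", "baited", "reward_magnitude") %in%
                  names(feeders)))
  if (anyDuplicated(feeders$label))
    stop("feeder labels must be unique")
  if (any(feeders$reward_magnitude < 0))
    stop("reward magnitudes must be non-negative")
  if (any((feeders$reward_magnitude == 0) & feeders$baited) ||
      any((feeders$reward_magnitude > 0) & !feeders$baited))
    stop("reward_magnitude must be zero exactly when a feeder is not baited")
  arena <- structure(list(shape = shape, radius_m = radius_m,
                          extent_m = extent_m, feeders = feeders),
                     class = "arena")
  if (nrow(feeders) && !all(points_in_arena(cbind(feeders$x, feeders$y), arena)))
    stop("all feeders must lie inside the arena boundary")
  arena
}

#' Define one or more feeders
#'
#' @param label Character label(s), unique within an arena. Baited feeders in
#'   a task are conventionally labelled `A`, `B`, ... in task (visit) order.
#' @param x,y Feeder coordinates in meters, origin at the arena center.
#' @param baited Logical; does the feeder hold a food reward?
#' @param reward_magnitude Reward size. Defaults to 1 for baited feeders and
#'   0 otherwise; a value of 0 for a baited feeder (or positive for an
#'   unbaited one) is rejected.
#' @return A data frame of feeders.
#' @export
feeder <- function(label, x, y, baited = FALSE,
                   reward_magnitude = ifelse(baited, 1, 0)) {
  data.frame(label = as.character(label), x = x, y = y, baited = baited,
             reward_magnitude = reward_magnitude,
             stringsAsFactors = FALSE)
}

empty_feeders <- function() {
  data.frame(label = character(), x = numeric(), y = numeric(),
             baited = logical(), reward_magnitude = numeric(),
             stringsAsFactors = FALSE)
}

points_in_arena <- function(pts, arena, tol = 1e-9) {
  if (arena$shape == "circular") {
    sqrt(pts[, 1]^2 + pts[, 2]^2) <= arena$radius_m + tol
  } else {
    abs(pts[, 1]) <= arena$extent_m[1] / 2 + tol &
      abs(pts[, 2]) <= arena$extent_m[2] / 2 + tol
  }
}

#' @export
print.arena <- function(x, ...) {
  dim <- if (x$shape == "circular") sprintf("radius %.2f m", x$radius_m)
         else sprintf("%.2f x %.2f m", x$extent_m[1], x$extent_m[2])
  cat(sprintf("<arena> %s, %s; %d feeders (%d baited)\n", x$shape, dim,
              nrow(x$feeders), sum(x$feeders$baited)))
  invisible(x)
}

#' Place feeders on an Archimedean spiral
#'
#' Distributes `n` feeders along an Archimedean spiral inscribed in the
#' arena, mimicking the 21-feeder spiral layout of the open-field foraging
#' task. Unbaited feeders are labelled `F01`, `F02`, ... from the spiral
#' origin outwards; the baited subset is relabelled `A`, `B`, ... in task
#' order.
#'
#' The task only constrains the layout topologically (which feeders are
#' baited and their relative distances), so the spiral pitch and start angle
#' are fixed, documented constants: the spiral makes `turns` full turns and
#' its outermost feeder sits at 95% of the arena radius.
#'
#' @param n Number of feeders (>= 1).
#' @param arena An [arena_config()]; its feeders are replaced.
#' @param baited Named integer vector mapping task labels to spiral indices,
#'   e.g. `c(A = 9, B = 14, ...)`. Labels are assigned in the order given.
#' @param magnitudes Optional named numeric vector of reward magnitudes per
#'   baited label (default 1 for every baited feeder).
#' @param turns Number of spiral turns (default 2).
#' @return The arena with `n` spiral feeders.
#' @export
spiral_feeders <- function(n, arena = arena_config("circular"),
                           baited = integer(), magnitudes = NULL,
                           turns = 2) {
  stopifnot(n >= 1)
  if (length(baited)) {
    if (is.null(names(baited)) || any(!nzchar(names(baited))))
      stop("'baited' must be a named vector: task label -> spiral index")
    if (any(baited < 1 | baited > n))
      stop("baited feeder index outside 1..n")
  }
  if (!is.null(magnitudes)) {
    bad <- setdiff(names(magnitudes), names(baited))
    if (length(bad))
      stop("unknown baited label(s): ", paste(bad, collapse = ", "))
  }
  rmax <- if (arena$shape == "circular") 0.95 * arena$radius_m
          else 0.95 * min(arena$extent_m) / 2
  t <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
  theta <- turns * 2 * pi * t
  r <- rmax * t
  lab <- sprintf("F%02d", seq_len(n))
  bait <- logical(n)
  mag <- numeric(n)
  for (i in seq_along(baited)) {
    k <- baited[[i]]
    lab[k] <- names(baited)[i]
    bait[k] <- TRUE
    mag[k] <- if (!is.null(magnitudes) && names(baited)[i] %in% names(magnitudes))
      magnitudes[[names(baited)[i]]] else 1
  }
  arena$feeders <- data.frame(label = lab, x = r * cos(theta),
                              y = r * sin(theta), baited = bait,
                              reward_magnitude = mag,
                              stringsAsFactors = FALSE)
  arena_config(arena$shape, arena$radius_m, arena$extent_m, arena$feeders)
}

#' Construct a trajectory object
#'
#' A trajectory is a time-ordered sequence of 2D points sampled at `dt`
#' seconds per step (default 5 ms, a 200 Hz update rate) with a spatial
#' resolution of `resolution` points per meter along the path. Feeder visits
#' are tagged by time index.
#'
#' @param points Numeric n x 2 matrix of (x, y) coordinates in meters.
#' @param dt Seconds per sample. Default 0.005.
#' @param resolution Points per meter. Default 20.
#' @param tags Data frame with columns `index` (time index) and `label`
#'   (feeder label), possibly empty.
#' @param arena Optional arena; when given, all points are checked to lie
#'   inside it.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(points, dt = 0.005, resolution = 20,
                       tags = data.frame(index = integer(),
                                         label = character()),
                       arena = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 2 || ncol(points) != 2)
    stop("a trajectory needs at least 2 points with 2 coordinates each")
  step <- sqrt(rowSums(diff(points)^2))
  if (any(step > 1 / resolution + 1e-9))
    stop("consecutive points exceed the sampling resolution spacing")
  if (!is.null(arena) && !all(points_in_arena(points, arena)))
    stop("trajectory leaves the arena")
  if (nrow(tags) && (any(tags$index < 1) || any(tags$index > nrow(points))))
    stop("tag index outside the trajectory")
  structure(list(points = unname(points), dt = dt, resolution = resolution,
                 tags = tags),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d samples (%.1f s at %.0f Hz), %.2f m, tags: %s\n",
              nrow(x$points), nrow(x$points) * x$dt, 1 / x$dt,
              path_length(x),
              if (nrow(x$tags)) paste(x$tags$label, collapse = "")
              else "none"))
  invisible(x)
}

#' Number of samples in a trajectory
#' @param traj A [trajectory()].
#' @export
n_samples <- function(traj) nrow(traj$points)

#' Total path length of a trajectory in meters
#' @param traj A [trajectory()] or an n x 2 point matrix.
#' @export
path_length <- function(traj) {
  pts <- if (inherits(traj, "trajectory")) traj$points else as.matrix(traj)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Reverse a trajectory in time
#'
#' Flips the point order and remaps the visit tags accordingly. Reversing
#' twice is the identity.
#' @param traj A [trajectory()].
#' @export
reverse_trajectory <- function(traj) {
  n <- n_samples(traj)
  tags <- traj$tags
  if (nrow(tags)) {
    tags$index <- n + 1L - tags$index
    tags <- tags[order(tags$index), , drop = FALSE]
    rownames(tags) <- NULL
  }
  trajectory(traj$points[n:1, , drop = FALSE], dt = traj$dt,
             resolution = traj$resolution, tags = tags)
}

#' Idealized piecewise-linear trajectory through waypoints
#'
#' Builds the idealized representation of a run: straight segments between
#' successive waypoints, sampled at `resolution` points per meter with both
#' endpoints included. Waypoints may be feeder labels (looked up in the
#' arena) or explicit coordinates; visited feeders are tagged at the sample
#' closest to the feeder.
#'
#' Zero-length segments (two identical consecutive waypoints) are rejected.
#'
#' @param waypoints Character vector of feeder labels, or an m x 2 matrix of
#'   points.
#' @param arena An [arena_config()]; required when waypoints are labels.
#' @param resolution Points per meter. Default 20.
#' @param dt Seconds per sample. Default 0.005.
#' @return A [trajectory()], tagged at visited feeders.
#' @examples
#' a <- arena_config("rectangular",
#'                   feeders = feeder(c("A", "B"), c(-0.5, 0.5), c(0, 0),
#'                                    baited = c(TRUE, TRUE)))
#' tr <- make_trajectory(c("A", "B"), a)
#' path_length(tr)
#' @export
make_trajectory <- function(waypoints, arena = NULL, resolution = 20,
                            dt = 0.005) {
  if (is.character(waypoints)) {
    if (is.null(arena)) stop("an arena is required to resolve feeder labels")
    idx <- match(waypoints, arena$feeders$label)
    if (anyNA(idx))
      stop("unknown feeder label(s): ",
           paste(waypoints[is.na(idx)], collapse = ", "))
    wp <- cbind(arena$feeders$x[idx], arena$feeders$y[idx])
    labels <- waypoints
  } else {
    wp <- as.matrix(waypoints)
    labels <- if (!is.null(arena) && nrow(arena$feeders)) {
      d <- outer(wp[, 1], arena$feeders$x, "-")^2 +
        outer(wp[, 2], arena$feeders$y, "-")^2
      hit <- apply(d, 1, function(r) if (min(r) < 1e-12) which.min(r) else NA)
      ifelse(is.na(hit), NA, arena$feeders$label[hit])
    } else rep(NA_character_, nrow(wp))
  }
  if (nrow(wp) < 2) stop("at least 2 waypoints are required")
  if (!is.null(arena) && !all(points_in_arena(wp, arena)))
    stop("waypoint outside the arena")
  seg_len <- sqrt(rowSums(diff(wp)^2))
  if (any(seg_len == 0)) stop("zero-length waypoint segment")
  pts <- list()
  tag_idx <- integer(nrow(wp))
  tag_idx[1] <- 1L
  total <- 0L
  for (i in seq_len(nrow(wp) - 1)) {
    nseg <- max(1L, ceiling(seg_len[i] * resolution - 1e-9))
    tt <- seq(0, 1, length.out = nseg + 1)[-1]
    seg <- cbind(wp[i, 1] + (wp[i + 1, 1] - wp[i, 1]) * tt,
                 wp[i, 2] + (wp[i + 1, 2] - wp[i, 2]) * tt)
    pts[[i]] <- seg
    total <- total + nseg
    tag_idx[i + 1] <- total + 1L
  }
  pts <- rbind(wp[1, , drop = FALSE], do.call(rbind, pts))
  keep <- !is.na(labels)
  trajectory(pts, dt = dt, resolution = resolution,
             tags = data.frame(index = tag_idx[keep],
                               label = labels[keep],
                               stringsAsFactors = FALSE),
             arena = arena)
}

#' Instantaneous reward signal along a trajectory
#'
#' The replay model only needs a coarse reward signal: `R(t)` equals the
#' reward magnitude of the baited feeder tagged at time index `t`, and 0
#' everywhere else.
#'
#' @param traj A tagged [trajectory()].
#' @param arena The [arena_config()] holding the feeder baiting.
#' @return Numeric vector of length `n_samples(traj)`.
#' @export
make_reward_signal <- function(traj, arena) {
  r <- numeric(n_samples(traj))
  if (nrow(traj$tags)) {
    f <- arena$feeders
    for (i in seq_len(nrow(traj$tags))) {
      j <- match(traj$tags$label[i], f$label)
      if (!is.na(j) && f$baited[j])
        r[traj$tags$index[i]] <- f$reward_magnitude[j]
    }
  }
  r
}
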