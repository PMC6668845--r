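#' Read and write trajectory files
#'
#' Trajectories are stored as comma-delimited text with a header line and
#' one row per sample: columns `t` (seconds), `x`, `y` (meters) and an
#' optional `tag` column holding the feeder label at tagged samples (empty
#' elsewhere). The round trip preserves points, sampling metadata and tags.
#'
#' @param traj A [trajectory()].
#' @param path File path.
#' @return `read_trajectory` returns a [trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  n <- n_samples(traj)
  tag <- character(n)
  if (nrow(traj$tags)) tag[traj$tags$index] <- traj$tags$label
  df <- data.frame(t = (seq_len(n) - 1) * traj$dt,
                   x = traj$points[, 1], y = traj$points[, 2], tag = tag)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_trajectory
#' @param resolution Points per meter recorded in the rebuilt object.
#' @export
read_trajectory <- function(path, resolution = 20) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("t", "x", "y") %in% names(df)))
    stop("trajectory file needs columns t, x, y")
  dt <- if (nrow(df) > 1) df$t[2] - df$t[1] else 0.005
  tags <- if ("tag" %in% names(df)) {
    keep <- !is.na(df$tag) & nzchar(df$tag)
    data.frame(index = which(keep), label = df$tag[keep],
               stringsAsFactors = FALSE)
  } else data.frame(index = integer(), label = character())
  trajectory(cbind(df$x, df$y), dt = dt, resolution = resolution,
             tags = tags)
}

#' Read and write arena configurations
#'
#' Arena and feeder definitions are stored as JSON with keys `shape`,
#' `radius_m`, `extent_m` and a `feeders` table (columns label, x, y,
#' baited, reward_magnitude).
#'
#' @param arena An [arena_config()].
#' @param path File path.
#' @return `read_arena` returns an [arena_config()].
#' @export
write_arena <- function(arena, path) {
  jsonlite::write_json(list(shape = arena$shape, radius_m = arena$radius_m,
                            extent_m = arena$extent_m,
                            feeders = arena$feeders),
                       path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_arena
#' @export
read_arena <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  feeders <- if (length(x$feeders)) as.data.frame(x$feeders)
             else empty_feeders()
  arena_config(x$shape, radius_m = x$radius_m, extent_m = x$extent_m,
               feeders = feeders)
}

#' Read and write activation rasters
#'
#' Rasters (time x cells matrices) are stored as comma-delimited text, one
#' row per time step, no header.
#'
#' @param raster An [encode_trajectory()] raster.
#' @param path File path.
#' @return `read_raster` returns the raster matrix.
#' @export
write_raster <- function(raster, path) {
  utils::write.table(unclass(raster), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  out <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(out) <- NULL
  class(out) <- c("activation_raster", class(out))
  out
}

#' Write a trajectory histogram as a delimited text grid
#'
#' @param hist A [trajectory_histogram()].
#' @param path File path.
#' @export
write_histogram <- function(hist, path) {
  utils::write.table(hist$counts, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
}
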