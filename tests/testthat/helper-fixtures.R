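# Shared fixtures: everything is built in code at test time.

# a small 4 x 4 place-field grid over a 1 x 1 m box
small_grid <- function() make_grid(4, 4, extent = c(-0.5, 0.5, -0.5, 0.5))

# a rectangular arena with two baited feeders on the x axis
two_feeder_arena <- function() {
  arena_config("rectangular", extent_m = c(2, 2),
               feeders = rbind(feeder("A", -0.5, 0, baited = TRUE),
                               feeder("B", 0.5, 0, baited = TRUE)))
}

# small reservoir for fast unit tests
small_params <- function(n_units = 60, k_in = 16, ...) {
  reservoir_params(n_units = n_units, k_in = k_in, ...)
}

# independent brute-force discrete Frechet oracle: recursive enumeration of
# all monotone couplings (exponential, fine for curves of <= 5 points)
frechet_brute <- function(A, B) {
  d <- function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))
  rec <- function(i, j) {
    here <- d(i, j)
    if (i == 1 && j == 1) return(here)
    prev <- Inf
    if (i > 1) prev <- min(prev, rec(i - 1, j))
    if (j > 1) prev <- min(prev, rec(i, j - 1))
    if (i > 1 && j > 1) prev <- min(prev, rec(i - 1, j - 1))
    max(here, prev)
  }
  rec(nrow(A), nrow(B))
}

# hand-built replay episode from explicit index windows over a raster
manual_episode <- function(windows, raster) {
  snippets <- lapply(windows, function(tau)
    list(indices = tau, source = 1L,
         patterns = t(raster[tau, , drop = FALSE])))
  structure(list(snippets = snippets,
                 total_samples = sum(lengths(windows)),
                 n_sources = 1L),
            class = "replay_episode")
}
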