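#' Replay model parameters
#'
#' Parameters of the hippocampal snippet-replay generative model. A replay
#' episode is bounded by a time budget `budget` counted in samples (one
#' sample = one 5 ms update); with the defaults `budget = 10000` and
#' `snippet_length = 10` an episode holds 1000 snippets, matching the
#' ecological estimate of replay volume during a 2-5 minute inter-trial
#' interval.
#'
#' `alpha_td`, `gamma` and `epsilon` govern the temporal-difference reward
#' propagation that shapes the replay likelihood; `beta_learn` and
#' `beta_generate` are the probabilities of replaying a snippet in reverse
#' order during the estimation and the generation phase respectively.
#'
#' @param epsilon Upper bound of the small positive random initialization of
#'   the reward prediction. Default 0.01.
#' @param alpha_td TD learning rate in \[0, 1\] (0 degenerates to the
#'   identity update). Default 0.1.
#' @param gamma Discount rate in \[0, 1). Default 0.9.
#' @param beta_learn Reverse-replay rate during learning, in \[0, 1\].
#'   Default 0.5.
#' @param beta_generate Reverse-replay rate during generation, in \[0, 1\].
#'   Default 0.
#' @param snippet_length Snippet length `s` in samples (>= 2). Default 10.
#' @param budget Time budget `T` in samples (>= `snippet_length`).
#'   Default 10000.
#' @return An object of class `replay_params`.
#' @export
replay_params <- function(epsilon = 0.01, alpha_td = 0.1, gamma = 0.9,
                          beta_learn = 0.5, beta_generate = 0,
                          snippet_length = 10, budget = 10000) {
  stopifnot(epsilon > 0, alpha_td >= 0, alpha_td <= 1,
            gamma >= 0, gamma < 1,
            beta_learn >= 0, beta_learn <= 1,
            beta_generate >= 0, beta_generate <= 1,
            snippet_length >= 2, budget >= snippet_length)
  structure(list(epsilon = epsilon, alpha_td = alpha_td, gamma = gamma,
                 beta_learn = beta_learn, beta_generate = beta_generate,
                 snippet_length = snippet_length, budget = budget),
            class = "replay_params")
}

#' Initialize the reward prediction
#'
#' Draws the per-time-index reward prediction `V(i) ~ U[0, epsilon)`
#' independently for every sample of a trajectory. The small positive
#' initialization guarantees that the normalized replay likelihood is
#' defined before any reward has been propagated.
#'
#' @param n Trajectory length in samples.
#' @param epsilon Upper bound of the initial values (> 0).
#' @return Numeric vector `V` of length `n`.
#' @export
replay_initialize <- function(n, epsilon = 0.01) {
  stopifnot(n >= 1)
  if (epsilon <= 0)
    stop("epsilon must be positive (an all-zero V cannot be normalized)")
  stats::runif(n, 0, epsilon)
}

#' Snippet replay likelihood
#'
#' Normalizes the reward prediction into the sampling distribution used to
#' draw snippet start indices: `P(i) = V(i) / sum(V)`.
#'
#' @param v Numeric reward-prediction vector with `sum(v) > 0`.
#' @return Numeric probability vector summing to 1.
#' @export
replay_likelihood <- function(v) {
  s <- sum(v)
  if (s <= 0) stop("cannot normalize an all-zero reward prediction")
  v / s
}

# Draw one snippet index window: start index sampled from P, direction
# reverse with probability beta. Windows are clamped at the trajectory ends
# and always contain at most s indices.
draw_snippet_indices <- function(p, s, beta) {
  n <- length(p)
  t0 <- sample.int(n, 1, prob = p)
  if (stats::runif(1) < beta) t0:max(1L, t0 - s + 1L)
  else t0:min(n, t0 + s - 1L)
}

#' Learn the reward prediction by replayed TD propagation
#'
#' Repeatedly draws snippet index windows (start sampled from the current
#' replay likelihood, direction reverse with probability `beta_learn`) and
#' applies the one-step temporal-difference update along each window,
#' \deqn{V(\tau_i) \leftarrow \alpha\,(R(\tau_{i-1}) + \gamma V(\tau_{i-1}))
#'   + (1 - \alpha)\,V(\tau_i),}
#' until the time budget is spent. The window direction acts as the
#' propagation vector: reverse windows move reward information backwards in
#' trajectory time, forward windows move it forward. Truncated windows at
#' the trajectory ends spend only their true length from the budget.
#'
#' @param reward Numeric instantaneous reward signal `R(t)` (see
#'   [make_reward_signal()]).
#' @param v Numeric reward prediction, same length as `reward` (see
#'   [replay_initialize()]).
#' @param params A [replay_params()]; uses `alpha_td`, `gamma`,
#'   `beta_learn`, `snippet_length` and `budget`.
#' @return The updated reward prediction vector.
#' @export
replay_learn <- function(reward, v, params = replay_params()) {
  if (length(reward) != length(v))
    stop("reward and reward prediction must have the same length")
  if (sum(v) <= 0) stop("cannot normalize an all-zero reward prediction")
  alpha <- params$alpha_td
  gamma <- params$gamma
  s <- params$snippet_length
  budget <- params$budget
  while (budget > 0) {
    tau <- draw_snippet_indices(replay_likelihood(v), s, params$beta_learn)
    if (length(tau) >= 2)
      for (i in 2:length(tau))
        v[tau[i]] <- alpha * (reward[tau[i - 1]] + gamma * v[tau[i - 1]]) +
          (1 - alpha) * v[tau[i]]
    budget <- budget - length(tau)
  }
  v
}

#' Generate a replay episode of snippets
#'
#' Samples snippets i.i.d. from the replay likelihood until the time budget
#' is exhausted (the last snippet may overshoot the budget by at most
#' `snippet_length - 1` samples). Each snippet carries its time-index window
#' and the corresponding slice of the activation raster; reverse snippets
#' (drawn with probability `beta_generate`) carry time-reversed patterns.
#'
#' Several source trajectories can be consolidated in one episode by passing
#' lists: each snippet first picks a source with probability proportional to
#' that source's total reward prediction `sum(V)`, then a start index within
#' the source from its normalized likelihood.
#'
#' @param raster An `activation_raster` (see [encode_trajectory()]), or a
#'   list of rasters for multi-source episodes.
#' @param v Reward-prediction vector, or a list of vectors matching
#'   `raster`.
#' @param params A [replay_params()]; uses `beta_generate`,
#'   `snippet_length` and `budget`.
#' @return An object of class `replay_episode`: a list with `snippets` (each
#'   a list with `indices`, `source`, `patterns`), `total_samples` and
#'   `n_sources`.
#' @examples
#' g <- make_grid()
#' sc <- scenario("fig1_abcde")
#' ras <- encode_trajectory(sc$trajectory, g)
#' set.seed(1)
#' ep <- replay_generate(ras, rep(1, nrow(ras)),
#'                       replay_params(budget = 100))
#' length(ep$snippets)
#' @export
replay_generate <- function(raster, v, params = replay_params()) {
  rasters <- if (is.list(raster)) raster else list(raster)
  vs <- if (is.list(v)) v else list(v)
  if (length(rasters) != length(vs))
    stop("need one reward prediction per raster")
  for (j in seq_along(rasters))
    if (nrow(rasters[[j]]) != length(vs[[j]]))
      stop("raster ", j, " and its reward prediction differ in length")
  sum_v <- vapply(vs, sum, numeric(1))
  if (any(sum_v <= 0)) stop("cannot normalize an all-zero reward prediction")
  ps <- lapply(vs, replay_likelihood)
  s <- params$snippet_length
  budget <- params$budget
  snippets <- list()
  total <- 0L
  while (total < budget) {
    src <- if (length(ps) == 1) 1L else sample.int(length(ps), 1, prob = sum_v)
    tau <- draw_snippet_indices(ps[[src]], s, params$beta_generate)
    snippets[[length(snippets) + 1L]] <-
      list(indices = tau, source = src,
           patterns = t(rasters[[src]][tau, , drop = FALSE]))
    total <- total + length(tau)
  }
  structure(list(snippets = snippets, total_samples = total,
                 n_sources = length(rasters)),
            class = "replay_episode")
}

#' @export
print.replay_episode <- function(x, ...) {
  rev_frac <- mean(vapply(x$snippets, function(s) s$indices[1] >
                            s$indices[length(s$indices)], logical(1)))
  cat(sprintf("<replay_episode> %d snippets, %d samples, %d source(s), %.0f%% reverse\n",
              length(x$snippets), x$total_samples, x$n_sources,
              100 * rev_frac))
  invisible(x)
}

#' Per-index snippet coverage counts
#'
#' Counts, for every trajectory time index, how many replayed snippets cover
#' it. The counts over all indices sum to the episode's total sample count.
#'
#' @param episode A [replay_generate()] episode.
#' @param n Trajectory length (number of time indices).
#' @param source Which source trajectory to count (default 1).
#' @return Integer vector of length `n`.
#' @export
snippet_histogram <- function(episode, n, source = 1) {
  counts <- integer(n)
  for (s in episode$snippets) {
    if (s$source != source) next
    counts[s$indices] <- counts[s$indices] + 1L
  }
  counts
}

#' Serialize a replay episode to a data frame
#'
#' Patterns are re-derivable from the raster, so only the index windows are
#' stored: one row per snippet with its source trajectory, start and end
#' index (start > end encodes a reverse snippet). The inverse operation is
#' [episode_from_df()].
#'
#' @param episode A [replay_generate()] episode.
#' @return A data frame with columns `snippet`, `source`, `start`, `end`.
#' @export
episode_to_df <- function(episode) {
  data.frame(
    snippet = seq_along(episode$snippets),
    source = vapply(episode$snippets, function(s) s$source, integer(1)),
    start = vapply(episode$snippets, function(s) s$indices[1], integer(1)),
    end = vapply(episode$snippets,
                 function(s) s$indices[length(s$indices)], integer(1)))
}

#' Rebuild a replay episode from its serialized form
#'
#' @param df A data frame as produced by [episode_to_df()].
#' @param raster A raster or list of rasters to slice the patterns from.
#' @return A `replay_episode`.
#' @export
episode_from_df <- function(df, raster) {
  rasters <- if (is.list(raster)) raster else list(raster)
  snippets <- lapply(seq_len(nrow(df)), function(i) {
    tau <- df$start[i]:df$end[i]
    list(indices = tau, source = df$source[i],
         patterns = t(rasters[[df$source[i]]][tau, , drop = FALSE]))
  })
  structure(list(snippets = snippets,
                 total_samples = sum(abs(df$end - df$start) + 1L),
                 n_sources = length(rasters)),
            class = "replay_episode")
}
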