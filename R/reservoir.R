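#' Reservoir network parameters
#'
#' The prefrontal-cortex model is a reservoir (echo state network) of
#' `n_units` leaky-integrator tanh neurons with fixed random feed-forward
#' and recurrent weights; only the readout is trained. The membrane
#' potential follows the forward-Euler leaky integration
#' \deqn{P(t_n) = h\,U(t_n) + (1 - h)\,P(t_{n-1}),}
#' where `h` is the leak rate (the inverse membrane time constant) and `U`
#' sums the feed-forward and recurrent drive. Firing rates are
#' `tanh(P - theta_res)`; the readout is `tanh(W_ro X - theta_ro)` and is
#' trained online with the Widrow-Hoff delta rule on mini-batches of
#' `batch_size` steps.
#'
#' Defaults for quantities the task does not pin down numerically
#' (`leak_rate`, `learning_rate`, `k_scale`, `reset_amplitude`) are the
#' package's own calibration, chosen once for stable single-pass delta-rule
#' convergence (see the methods vignette) and exposed here.
#'
#' @param n_units Reservoir size N. Default 1000.
#' @param k_in Input dimension K (number of place cells). Default 256.
#' @param leak_rate Leak rate `h` in (0, 1]. Default 0.5.
#' @param k_scale Recurrent weight scale: `W_rec ~ U[-1, 1] * k_scale / N`.
#'   Default `sqrt(3 * n_units)`, which sets the spectral radius of `W_rec`
#'   to approximately 1 (U\[-1,1\] entries have variance 1/3, so the
#'   circular-law radius of the scaled matrix is `k_scale * sqrt(1/(3 N))`).
#' @param theta_res,theta_ro Activation bias (threshold) of the reservoir
#'   and readout units. Both 0 by default.
#' @param learning_rate Readout learning rate `alpha_ro`. Default 0.005.
#' @param batch_size Mini-batch length `b` for the delta rule. Default 32.
#' @param reset_amplitude Bound of the uniform random state reset applied
#'   between snippets. Default 0.01.
#' @return An object of class `reservoir_params`.
#' @export
reservoir_params <- function(n_units = 1000, k_in = 256, leak_rate = 0.5,
                             k_scale = sqrt(3 * n_units), theta_res = 0,
                             theta_ro = 0, learning_rate = 0.005,
                             batch_size = 32, reset_amplitude = 0.01) {
  stopifnot(n_units >= 1, k_in >= 1, leak_rate > 0, leak_rate <= 1,
            k_scale > 0, learning_rate > 0, batch_size >= 1,
            reset_amplitude >= 0)
  structure(list(n_units = n_units, k_in = k_in, leak_rate = leak_rate,
                 k_scale = k_scale, theta_res = theta_res,
                 theta_ro = theta_ro, learning_rate = learning_rate,
                 batch_size = batch_size,
                 reset_amplitude = reset_amplitude),
            class = "reservoir_params")
}

#' Initialize a reservoir network
#'
#' Feed-forward weights are drawn from `U[-1, 1]`; recurrent weights from
#' `U[-1, 1]` scaled by `k_scale / N` with self-connections forced to zero.
#' Both are fixed after construction. The readout weight matrix starts at
#' zero and is the only trainable part.
#'
#' @param params A [reservoir_params()].
#' @return An object of class `reservoir` with weight matrices `w_ffwd`
#'   (N x K), `w_rec` (N x N, zero diagonal), `w_ro` (K x N) and the
#'   `params`.
#' @examples
#' set.seed(1)
#' net <- init_network(reservoir_params(n_units = 50, k_in = 16))
#' all(diag(net$w_rec) == 0)
#' @export
init_network <- function(params = reservoir_params()) {
  n <- params$n_units
  k <- params$k_in
  w_ffwd <- matrix(stats::runif(n * k, -1, 1), n, k)
  w_rec <- matrix(stats::runif(n * n, -1, 1), n, n) * (params$k_scale / n)
  diag(w_rec) <- 0
  structure(list(w_ffwd = w_ffwd, w_rec = w_rec,
                 w_ro = matrix(0, k, n), params = params),
            class = "reservoir")
}

#' @export
print.reservoir <- function(x, ...) {
  cat(sprintf("<reservoir> N = %d units, K = %d inputs, h = %.2f, trained readout norm %.3g\n",
              x$params$n_units, x$params$k_in, x$params$leak_rate,
              sqrt(sum(x$w_ro^2))))
  invisible(x)
}

#' Estimated spectral radius of the recurrent weight matrix
#'
#' Power iteration on `W_rec`; with the default `k_scale` the radius is
#' close to 1, the usual echo-state operating point.
#'
#' @param net A [init_network()] reservoir.
#' @param iter Number of power iterations. Default 100.
#' @return Estimated modulus of the leading eigenvalue.
#' @export
spectral_radius <- function(net, iter = 100) {
  n <- nrow(net$w_rec)
  v <- rep(1 / sqrt(n), n)
  lam <- 0
  for (i in seq_len(iter)) {
    v2 <- net$w_rec %*% v
    lam <- sqrt(sum(v2^2))
    if (lam == 0) return(0)
    v <- v2 / lam
  }
  lam
}

#' Reset the reservoir state between snippets
#'
#' Sets the membrane potentials and readout to small uniform random values
#' centered on zero, decorrelating the network from the previous snippet
#' (a stand-in for the long inter-replay interval).
#'
#' @param params A [reservoir_params()].
#' @return An object of class `reservoir_state` with `p_res`, `x_res`,
#'   `x_ro`.
#' @export
reset_state <- function(params = reservoir_params()) {
  amp <- params$reset_amplitude
  p <- stats::runif(params$n_units, -amp, amp)
  structure(list(p_res = p, x_res = tanh(p - params$theta_res),
                 x_ro = stats::runif(params$k_in, -amp, amp)),
            class = "reservoir_state")
}

#' Advance the reservoir by one step
#'
#' Applies the feed-forward and recurrent drive, the leaky membrane
#' integration and the tanh activations:
#' `U = W_ffwd x_in + W_rec x_res`, `P <- h U + (1 - h) P`,
#' `X_res = tanh(P - theta_res)`, `X_ro = tanh(W_ro X_res - theta_ro)`.
#'
#' @param net A [init_network()] reservoir.
#' @param state A `reservoir_state` (see [reset_state()]).
#' @param x_in Input activation pattern (length K).
#' @return The updated `reservoir_state`, with the housed intermediates
#'   `u_ffwd`, `u_rec`, `u_res` attached.
#' @export
reservoir_step <- function(net, state, x_in) {
  p <- net$params
  if (length(x_in) != p$k_in) stop("input dimension mismatch")
  u_ffwd <- drop(net$w_ffwd %*% x_in)
  u_rec <- drop(net$w_rec %*% state$x_res)
  u_res <- u_ffwd + u_rec
  p_res <- p$leak_rate * u_res + (1 - p$leak_rate) * state$p_res
  x_res <- tanh(p_res - p$theta_res)
  structure(list(p_res = p_res, x_res = x_res,
                 x_ro = drop(tanh(net$w_ro %*% x_res - p$theta_ro)),
                 u_ffwd = u_ffwd, u_rec = u_rec, u_res = u_res),
            class = "reservoir_state")
}

#' Widrow-Hoff delta-rule update of the readout weights
#'
#' Gradient-descent step on the mean squared readout error of a mini-batch,
#' through the tanh readout nonlinearity:
#' \deqn{W_{ro} \leftarrow W_{ro} - \alpha\, \overline{(X_{ro} - X_{des})
#'   \odot (1 - X_{ro}^2)\; X_{res}^\top},}
#' averaging over the batch. For a sufficiently small learning rate the
#' batch MSE is non-increasing on a repeated fixed batch.
#'
#' @param net A [init_network()] reservoir.
#' @param x_res_batch N x b matrix of reservoir states.
#' @param x_ro_batch K x b matrix of readout activations.
#' @param x_des_batch K x b matrix of desired outputs.
#' @return The network with updated `w_ro`.
#' @export
delta_update <- function(net, x_res_batch, x_ro_batch, x_des_batch) {
  b <- ncol(x_res_batch)
  if (b == 0) stop("empty batch")
  if (ncol(x_ro_batch) != b || ncol(x_des_batch) != b)
    stop("batch matrices must have the same number of columns")
  err <- (x_ro_batch - x_des_batch) * (1 - x_ro_batch^2)
  net$w_ro <- net$w_ro -
    (net$params$learning_rate / b) * err %*% t(x_res_batch)
  net
}

#' Train the readout on a replay episode
#'
#' Online single-pass training: for each snippet the state is reset, the
#' reservoir is driven with the snippet's patterns in replay order, and the
#' readout learns to predict the next pattern within the snippet
#' (`X_des(t_n) = X_in(t_{n+1})`). Delta-rule updates are applied every
#' `batch_size` steps, flushing the remainder at the snippet boundary so
#' that a batch never mixes two snippets. Snippets of length 1 carry no
#' next-step target and are skipped with a warning.
#'
#' @param net A [init_network()] reservoir.
#' @param episode A [replay_generate()] episode.
#' @return The trained network, with the per-snippet mean squared error
#'   trace attached as attribute `loss`.
#' @export
train_on_episode <- function(net, episode) {
  p <- net$params
  lens <- vapply(episode$snippets, function(s) length(s$indices), integer(1))
  if (any(lens < 2))
    warning(sum(lens < 2), " length-1 snippet(s) skipped (no next-step target)")
  patterns <- lapply(episode$snippets, function(s) s$patterns)
  fit <- cpp_train_on_episode(net$w_ffwd, net$w_rec, net$w_ro, patterns,
                              p$leak_rate, p$theta_res, p$theta_ro,
                              p$learning_rate, p$batch_size,
                              p$reset_amplitude)
  net$w_ro <- fit$w_ro
  attr(net, "loss") <- drop(fit$loss)
  net
}

#' Drive the reservoir with an input sequence (no learning)
#'
#' Teacher-forced run from a reset state; returns the full state and
#' readout traces. Used for non-autonomous evaluation and for state-space
#' analyses.
#'
#' @param net A [init_network()] reservoir.
#' @param inputs n x K matrix of activation patterns (rows = time).
#' @param reset Reset the state first (default TRUE; draws from the RNG).
#' @return A list with `x_res` (n x N), `x_ro` (n x K).
#' @export
drive_reservoir <- function(net, inputs, reset = TRUE) {
  p <- net$params
  p0 <- if (reset) stats::runif(p$n_units, -p$reset_amplitude,
                                p$reset_amplitude)
        else rep(0, p$n_units)
  out <- cpp_drive(net$w_ffwd, net$w_rec, net$w_ro, t(inputs),
                   p$leak_rate, p$theta_res, p$theta_ro, p0)
  list(x_res = t(out$x_res), x_ro = t(out$x_ro))
}

#' Reservoir state trajectories under snippet drive
#'
#' Drives the reservoir with every snippet of an episode (state reset
#' before each) and collects the reservoir state sequence per snippet.
#' These state trajectories are the raw material of the state-space
#' consolidation analysis (see [state_overlap()]).
#'
#' @param net A [init_network()] reservoir.
#' @param episode A [replay_generate()] episode.
#' @return A list of n_i x N state matrices, one per snippet.
#' @export
collect_states <- function(net, episode) {
  lapply(episode$snippets, function(s)
    drive_reservoir(net, t(s$patterns))$x_res)
}

#' Save / load a network checkpoint
#'
#' The checkpoint stores the weight tables and parameters in R's native
#' serialization format.
#'
#' @param net A [init_network()] reservoir.
#' @param path File path.
#' @return `load_network` returns the reservoir.
#' @export
save_network <- function(net, path) saveRDS(net, path)

#' @rdname save_network
#' @export
load_network <- function(path) readRDS(path)
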