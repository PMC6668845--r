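#' Specify a scripted experiment
#'
#' Bundles the population sizing, replay and reservoir parameters and the
#' master seed of one of the packaged experiments. All randomness derives
#' from `seed`, so a spec reproduces bit-for-bit. The full-scale settings
#' (population 1000, 10 runs each) are accepted but the defaults are scaled
#' down (population 50, 5 runs) to complete in minutes on one CPU.
#'
#' @param name One of `intact_sequence`, `consolidation_fig5`,
#'   `tmaze_fig6`, `recombination_fig7`, `reverse_fig8`, `shortcut_fig9`.
#' @param population Number of independently seeded networks. Default 50.
#' @param runs_per_net Autonomous generations per network. Default 5.
#' @param replay A [replay_params()].
#' @param reservoir A [reservoir_params()].
#' @param noise_m Spatial-filter score noise during generation.
#'   Default 2e-4 (about 1% of the typical candidate score spread).
#' @param reward_d T-maze reward magnitude at D (1 or 10). Default 1.
#' @param snippet_counts Episode sizes for the consolidation analysis.
#'   Default `c(100, 1000, 10000)` snippets.
#' @param duration_buffer Fractional duration margin for autonomous
#'   generation beyond the target length. Default 0.08.
#' @param seed Master seed. Default 1.
#' @param out_dir Optional directory for result artifacts (distance
#'   tables, histograms, comparison stats).
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(name = c("intact_sequence", "consolidation_fig5",
                                     "tmaze_fig6", "recombination_fig7",
                                     "reverse_fig8", "shortcut_fig9"),
                            population = 50, runs_per_net = 5,
                            replay = replay_params(),
                            reservoir = reservoir_params(),
                            noise_m = 2e-4, reward_d = 1,
                            snippet_counts = c(100, 1000, 10000),
                            duration_buffer = 0.08, seed = 1,
                            out_dir = NULL) {
  name <- match.arg(name)
  stopifnot(population >= 1, runs_per_net >= 1)
  structure(list(name = name, population = population,
                 runs_per_net = runs_per_net, replay = replay,
                 reservoir = reservoir, noise_m = noise_m,
                 reward_d = reward_d, snippet_counts = snippet_counts,
                 duration_buffer = duration_buffer, seed = seed,
                 out_dir = out_dir),
            class = "experiment_spec")
}

exp_log <- function(spec, stage) {
  message(sprintf("[%s seed=%d] %s", spec$name, spec$seed, stage))
}

# Per-net sub-seeds derived from the master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Reward-modulated replay + training pipeline for one network: learn one
# reward prediction per source trajectory, generate a mixed episode, train.
train_net_on_sources <- function(rasters, rewards, replay, reservoir,
                                 uniform = FALSE) {
  vs <- lapply(seq_along(rasters), function(j) {
    if (uniform) rep(1, nrow(rasters[[j]]))
    else replay_learn(rewards[[j]],
                      replay_initialize(nrow(rasters[[j]]), replay$epsilon),
                      replay)
  })
  episode <- replay_generate(rasters, vs, replay)
  net <- train_on_episode(init_network(reservoir), episode)
  list(net = net, vs = vs, episode = episode)
}

# Distances of a batch of generated trajectories to named references.
distances_to_refs <- function(trajs, refs) {
  out <- sapply(names(refs), function(nm)
    vapply(trajs, function(tr) discrete_frechet(tr, refs[[nm]])$value,
           numeric(1)))
  matrix(out, nrow = length(trajs),
         dimnames = list(NULL, names(refs)))
}

write_artifacts <- function(spec, result) {
  if (is.null(spec$out_dir)) return(invisible(NULL))
  dir.create(spec$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(result$comparison))
    write_comparison(result$comparison,
                     file.path(spec$out_dir, "comparison.csv"))
  if (!is.null(result$distances))
    utils::write.csv(as.data.frame(result$distances),
                     file.path(spec$out_dir, "distances.csv"),
                     row.names = FALSE)
  if (!is.null(result$histogram))
    write_histogram(result$histogram,
                    file.path(spec$out_dir, "histogram.csv"))
  invisible(NULL)
}

#' Run a scripted experiment
#'
#' Wires the whole pipeline for one of the packaged experiments:
#' scenario fixtures, place-cell encoding, reward-propagated replay,
#' reservoir training and population evaluation, returning the distance
#' groups and the headline statistical contrast. Deterministic given the
#' spec's seed.
#'
#' * `intact_sequence` — uniform replay of the efficient five-feeder tour;
#'   contrast: trained vs untrained distance-to-target.
#' * `consolidation_fig5` — reservoir state-space overlap between
#'   snippet-driven and intact-sequence state trajectories as the episode
#'   grows; no group contrast, returns the overlap table.
#' * `tmaze_fig6` — reward-modulated replay of ABC/ABD; contrast:
#'   distance-to-ABC vs distance-to-ABD of autonomous generations.
#' * `recombination_fig7` — reward-modulated replay of three inefficient
#'   tours; contrast: distance of autonomous generations to the never-
#'   experienced efficient tour vs to each training tour.
#' * `reverse_fig8` — recombination with one source experienced in the
#'   reverse direction; contrast: distance-to-target with 50% vs 0%
#'   reverse replay during generation.
#' * `shortcut_fig9` — two-loop maze, uniform replay at a given reverse
#'   rate; non-autonomous error on the full counter-clockwise outer loop,
#'   split into the side experienced in the congruent direction vs the
#'   side experienced only in the opposite direction.
#'
#' @param spec An [experiment_spec()].
#' @return A list with elements depending on the experiment; always
#'   includes `name`, `seed`, and where applicable `distances` (matrix or
#'   list of numeric vectors), `comparison` (a [compare_groups()] result
#'   or NULL) and `histogram`.
#' @export
run_experiment <- function(spec) {
  t0 <- proc.time()[3]
  exp_log(spec, "start")
  on.exit(exp_log(spec, sprintf("done in %.1f s", proc.time()[3] - t0)))
  switch(spec$name,
         intact_sequence = exp_intact(spec),
         consolidation_fig5 = exp_consolidation(spec),
         tmaze_fig6 = exp_tmaze(spec),
         recombination_fig7 = exp_recombination(spec),
         reverse_fig8 = exp_reverse(spec),
         shortcut_fig9 = exp_shortcut(spec))
}

exp_intact <- function(spec) {
  grid <- make_grid()
  sc <- scenario("fig1_abcde")
  ras <- encode_trajectory(sc$trajectory, grid)
  n_t <- n_samples(sc$trajectory)
  cfg <- generation_config(prime_steps = spec$replay$snippet_length,
                           max_steps = round((1 + spec$duration_buffer) * n_t),
                           noise_m = spec$noise_m)
  seeds <- derive_seeds(spec$seed, spec$population)
  d_tr <- d_un <- c()
  for (i in seq_len(spec$population)) {
    set.seed(seeds[i])
    fit <- train_net_on_sources(list(ras), list(sc$reward), spec$replay,
                                spec$reservoir, uniform = TRUE)
    untrained <- init_network(spec$reservoir)
    for (r in seq_len(spec$runs_per_net)) {
      g1 <- autonomous_generate(fit$net, grid, sc$trajectory, cfg)
      g0 <- autonomous_generate(untrained, grid, sc$trajectory, cfg)
      d_tr <- c(d_tr, discrete_frechet(g1, sc$trajectory)$value)
      d_un <- c(d_un, discrete_frechet(g0, sc$trajectory)$value)
    }
  }
  cmp <- compare_groups(list(trained = d_tr, untrained = d_un))
  res <- list(name = spec$name, seed = spec$seed,
              distances = cbind(trained = d_tr, untrained = d_un),
              comparison = cmp)
  write_artifacts(spec, res)
  res
}

exp_consolidation <- function(spec) {
  grid <- make_grid()
  sc <- scenario("fig1_abcde")
  ras <- encode_trajectory(sc$trajectory, grid)
  s <- spec$replay$snippet_length
  transient <- 3
  seeds <- derive_seeds(spec$seed, max(3, min(spec$population, 5)))
  rows <- list()
  for (i in seq_along(seeds)) {
    set.seed(seeds[i])
    net <- init_network(spec$reservoir)
    full <- drive_reservoir(net, ras)$x_res
    # project everything on the intact-sequence PCA plane once; stream the
    # snippet states through it so large episodes never sit in memory
    pca <- stats::prcomp(full, center = TRUE, rank. = 2)
    full2 <- pca$x[, 1:2, drop = FALSE]
    bbox <- apply(full2, 2, range)
    radius <- 0.05 * sqrt(sum((bbox[2, ] - bbox[1, ])^2))
    # one long replay episode; the smaller counts are its prefixes, i.e.
    # snapshots of the same replay process at increasing exposure
    counts <- sort(spec$snippet_counts)
    rp <- replay_params(epsilon = spec$replay$epsilon,
                        snippet_length = s, budget = max(counts) * s)
    ep <- replay_generate(ras, rep(1, nrow(ras)), rp)
    covered <- rep(FALSE, nrow(full2))
    near <- 0L
    total <- 0L
    next_count <- 1L
    for (k in seq_along(ep$snippets)) {
      if (next_count > length(counts)) break
      sn <- ep$snippets[[k]]
      if (length(sn$indices) > transient) {
        st <- drive_reservoir(net, t(sn$patterns))$x_res
        st <- st[-seq_len(transient), , drop = FALSE]
        st2 <- scale(st, center = pca$center, scale = FALSE) %*%
          pca$rotation[, 1:2]
        d2 <- outer(st2[, 1], full2[, 1], "-")^2 +
          outer(st2[, 2], full2[, 2], "-")^2
        hit <- d2 <= radius^2
        covered <- covered | apply(hit, 2, any)
        near <- near + sum(apply(hit, 1, any))
        total <- total + nrow(st2)
      }
      while (next_count <= length(counts) &&
             (k == counts[next_count] || k == length(ep$snippets))) {
        rows[[length(rows) + 1]] <- data.frame(
          seed = seeds[i], n_snippets = counts[next_count],
          overlap_coverage = mean(covered),
          overlap_snippet = near / total)
        next_count <- next_count + 1L
      }
    }
  }
  res <- list(name = spec$name, seed = spec$seed,
              overlap = do.call(rbind, rows), comparison = NULL)
  if (!is.null(spec$out_dir)) {
    dir.create(spec$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$overlap, file.path(spec$out_dir, "overlap.csv"),
                     row.names = FALSE)
  }
  res
}

exp_tmaze <- function(spec) {
  grid <- make_grid()
  sc_c <- scenario("tmaze_abc", reward_d = spec$reward_d)
  sc_d <- scenario("tmaze_abd", reward_d = spec$reward_d)
  rasters <- list(encode_trajectory(sc_c$trajectory, grid),
                  encode_trajectory(sc_d$trajectory, grid))
  rewards <- list(sc_c$reward, sc_d$reward)
  n_eval <- round((1 + spec$duration_buffer) *
                    mean(c(n_samples(sc_c$trajectory),
                           n_samples(sc_d$trajectory))))
  cfg <- generation_config(prime_steps = spec$replay$snippet_length,
                           max_steps = n_eval, noise_m = spec$noise_m)
  seeds <- derive_seeds(spec$seed, spec$population)
  d_abc <- d_abd <- c()
  trajs <- list()
  for (i in seq_len(spec$population)) {
    set.seed(seeds[i])
    fit <- train_net_on_sources(rasters, rewards, spec$replay,
                                spec$reservoir)
    gens <- random_walk(list(fit$net), grid, sc_c$trajectory, cfg,
                        spec$runs_per_net)
    trajs <- c(trajs, gens)
    d_abc <- c(d_abc, vapply(gens, function(g)
      discrete_frechet(g, sc_c$trajectory)$value, numeric(1)))
    d_abd <- c(d_abd, vapply(gens, function(g)
      discrete_frechet(g, sc_d$trajectory)$value, numeric(1)))
  }
  cmp <- compare_groups(list(ABC = d_abc, ABD = d_abd))
  res <- list(name = spec$name, seed = spec$seed,
              reward_d = spec$reward_d,
              distances = cbind(ABC = d_abc, ABD = d_abd),
              preference_abc = mean(d_abc < d_abd),
              comparison = cmp,
              histogram = trajectory_histogram(trajs, sc_c$arena))
  write_artifacts(spec, res)
  res
}

recombination_setup <- function(spec, grid, reverse_ebcda = FALSE) {
  names <- c("fig1_abced", "fig1_ebcda", "fig1_bacde")
  scns <- lapply(names, scenario)
  if (reverse_ebcda) {
    scns[[2]]$trajectory <- reverse_trajectory(scns[[2]]$trajectory)
    scns[[2]]$reward <- make_reward_signal(scns[[2]]$trajectory,
                                           scns[[2]]$arena)
  }
  target <- scenario("fig1_abcde")
  list(scns = scns,
       rasters = lapply(scns, function(s)
         encode_trajectory(s$trajectory, grid)),
       rewards = lapply(scns, `[[`, "reward"),
       target = target,
       refs = c(list(ABCDE = target$trajectory),
                stats::setNames(lapply(scns, `[[`, "trajectory"),
                                c("ABCED", "EBCDA", "BACDE"))))
}

run_recombination_population <- function(spec, grid, setup, beta_generate) {
  replay <- spec$replay
  replay$beta_generate <- beta_generate
  n_t <- n_samples(setup$target$trajectory)
  cfg <- generation_config(prime_steps = replay$snippet_length,
                           max_steps = round((1 + spec$duration_buffer) * n_t),
                           noise_m = spec$noise_m)
  seeds <- derive_seeds(spec$seed, spec$population)
  dist <- NULL
  trajs <- list()
  for (i in seq_len(spec$population)) {
    set.seed(seeds[i])
    fit <- train_net_on_sources(setup$rasters, setup$rewards, replay,
                                spec$reservoir)
    gens <- random_walk(list(fit$net), grid, setup$target$trajectory, cfg,
                        spec$runs_per_net)
    trajs <- c(trajs, gens)
    dist <- rbind(dist, distances_to_refs(gens, setup$refs))
  }
  list(distances = dist, trajs = trajs)
}

exp_recombination <- function(spec) {
  grid <- make_grid()
  setup <- recombination_setup(spec, grid)
  pop <- run_recombination_population(spec, grid, setup,
                                      spec$replay$beta_generate)
  cmp <- compare_groups(as.list(as.data.frame(pop$distances)))
  res <- list(name = spec$name, seed = spec$seed,
              distances = pop$distances, comparison = cmp,
              histogram = trajectory_histogram(pop$trajs,
                                               setup$target$arena))
  write_artifacts(spec, res)
  res
}

exp_reverse <- function(spec) {
  grid <- make_grid()
  setup <- recombination_setup(spec, grid, reverse_ebcda = TRUE)
  pop0 <- run_recombination_population(spec, grid, setup, 0)
  pop5 <- run_recombination_population(spec, grid, setup, 0.5)
  d0 <- pop0$distances[, "ABCDE"]
  d5 <- pop5$distances[, "ABCDE"]
  wt <- stats::wilcox.test(d5, d0, alternative = "less")
  res <- list(name = spec$name, seed = spec$seed,
              distances = list(beta_0 = d0, beta_0.5 = d5),
              comparison = compare_groups(list(beta_0 = d0,
                                               beta_0.5 = d5)),
              p_one_sided = wt$p.value)
  if (!is.null(spec$out_dir)) {
    dir.create(spec$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_comparison(res$comparison,
                     file.path(spec$out_dir, "comparison.csv"))
  }
  res
}

shortcut_eval <- function(spec, grid, beta_generate, seeds) {
  scl <- scenario("loop_left")
  scr <- scenario("loop_right")
  rasters <- list(encode_trajectory(scl$trajectory, grid),
                  encode_trajectory(scr$trajectory, grid))
  loop <- scenario("loop_outer_ccw")$trajectory
  replay <- spec$replay
  replay$beta_generate <- beta_generate
  cfg <- generation_config(prime_steps = replay$snippet_length)
  per_net <- lapply(seeds, function(sd) {
    set.seed(sd)
    fit <- train_net_on_sources(rasters, NULL, replay, spec$reservoir,
                                uniform = TRUE)
    ev <- non_autonomous_generate(fit$net, grid, loop, cfg)
    x_next <- loop$points[-1, 1]
    list(mean_error = mean(ev$error),
         right_error = mean(ev$error[x_next > 0.2]),
         left_error = mean(ev$error[x_next < -0.2]))
  })
  list(mean_error = vapply(per_net, `[[`, numeric(1), "mean_error"),
       right_error = vapply(per_net, `[[`, numeric(1), "right_error"),
       left_error = vapply(per_net, `[[`, numeric(1), "left_error"))
}

exp_shortcut <- function(spec) {
  grid <- make_grid()
  seeds <- derive_seeds(spec$seed, spec$population)
  ev <- shortcut_eval(spec, grid, spec$replay$beta_generate, seeds)
  cmp <- compare_groups(list(congruent_side = ev$left_error,
                             incongruent_side = ev$right_error))
  res <- list(name = spec$name, seed = spec$seed,
              beta_generate = spec$replay$beta_generate,
              errors = ev, comparison = cmp)
  if (!is.null(spec$out_dir)) {
    dir.create(spec$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_comparison(cmp, file.path(spec$out_dir, "comparison.csv"))
  }
  res
}

#' Sweep the reverse-replay rate
#'
#' Re-runs an experiment's evaluation at several reverse-replay generation
#' rates with shared per-network seeds across rates (paired comparisons),
#' reporting the [score()] of the error distribution per rate. Implemented
#' for the `shortcut_fig9` non-autonomous loop evaluation, where the
#' characteristic U-shape appears: mixed forward/reverse replay (rates
#' around 25-75%) outperforms pure forward (0%) and pure reverse (100%).
#'
#' @param spec An [experiment_spec()] with name `shortcut_fig9`.
#' @param rates Reverse rates in \[0, 1\].
#'   Default `c(0, 0.25, 0.5, 0.75, 1)`.
#' @return A data frame with one row per rate: `rate`, `mean`, `sd`,
#'   `score` of the per-network mean loop error.
#' @export
sweep_reverse_rate <- function(spec, rates = c(0, 0.25, 0.5, 0.75, 1)) {
  stopifnot(spec$name == "shortcut_fig9",
            all(rates >= 0), all(rates <= 1))
  grid <- make_grid()
  seeds <- derive_seeds(spec$seed, spec$population)
  rows <- lapply(rates, function(b) {
    ev <- shortcut_eval(spec, grid, b, seeds)
    data.frame(rate = b, mean = mean(ev$mean_error),
               sd = stats::sd(ev$mean_error), score = score(ev$mean_error))
  })
  do.call(rbind, rows)
}
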