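# snippetrc

Rats foraging among multiple baited feeders converge, within a handful of
trials, on near-shortest tours of the reward sites — an approximate
traveling-salesperson behavior. `snippetrc` simulates a systems-level
account of how that can work: awake hippocampal replay of short place-cell
sequence fragments ("snippets"), biased by reward and played in forward and
reverse order, trains a prefrontal sequence-learning network that
consolidates the fragments — and thereby composes efficient trajectories the
animal never actually ran.

The package is aimed at computational-neuroscience users who want to run,
probe or extend the model: every stage is an exported, documented function,
and the headline simulation experiments are scripted and seeded.

## Model core

* **Place-cell code** — locations `s` are encoded by a 16 x 16 grid of
  Gaussian place fields over a 2 x 2 m enclosure,
  `f_k(s) = exp(-||s - c_k||^2 / w_k)` with `w_k = r_k^2 / (-log Θ)`.
* **Reward-propagated replay** — a per-time-index reward prediction `V` is
  learned by replaying index windows (reverse with probability `β_learn`)
  under the TD-style update
  `V(τ_i) ← α (R(τ_{i-1}) + γ V(τ_{i-1})) + (1-α) V(τ_i)`;
  snippets are then drawn from the normalized likelihood `P = V / ΣV`
  within a sample budget `T` (defaults `T = 10000`, snippet length
  `s = 10`, i.e. 1000 snippets per episode).
* **Reservoir consolidation** — an echo-state network of 1000
  leaky-integrator tanh units (`P ← h·U + (1-h)·P`) with fixed random
  weights; only the readout is trained, online, with the tanh Widrow-Hoff
  delta rule on 32-step mini-batches, to predict the next place-cell
  pattern. State is reset between snippets.
* **Spatial filter** — the Bayesian decoder
  `s* = argmax_q P(q | η, s)` over a motion-constrained candidate set
  (≤ 10 cm per step, ±110° heading cone) that turns each noisy predicted
  pattern `η` into a clean next location, closing the sensory-motor loop.
* **Evaluation** — discrete Fréchet distance between generated and
  reference trajectories, the batch score `μ + σ`, Kruskal-Wallis group
  contrasts, and reservoir state-space overlap analyses.

## Worked example

Train one model on reward-biased replay of an inefficient tour and let it
run autonomously:

```r
library(snippetrc)
set.seed(1)

grid <- make_grid()                      # 16 x 16 place fields, 2 x 2 m
sc   <- scenario("fig1_abcde")           # efficient 5-feeder tour fixture
ras  <- encode_trajectory(sc$trajectory, grid)

ep  <- replay_generate(ras, rep(1, nrow(ras)), replay_params())
net <- train_on_episode(init_network(reservoir_params()), ep)

cfg <- generation_config(max_steps = round(1.08 * n_samples(sc$trajectory)),
                         noise_m = 2e-4)
gen <- autonomous_generate(net, grid, sc$trajectory, cfg)
discrete_frechet(gen, sc$trajectory)
#> discrete Frechet distance: 0.0365 (curves 67 / 62 points)
```

After 1000 replayed snippets the closed-loop trajectory tracks the 2.9 m
tour to within about 4 cm — less than the place-field grid spacing.

The scripted experiments reproduce the model's population-level results,
e.g. the recombination experiment (train on three inefficient tours, each
containing one efficient sub-path, and test which reference the generated
behavior resembles):

```r
res <- run_experiment(experiment_spec("recombination_fig7",
                                      population = 8, runs_per_net = 3,
                                      seed = 7))
res$comparison
#> Kruskal-Wallis chi-squared = 57.790, p = 1.74e-12
#>   group  n   mean      sd median  score
#> 1 ABCDE 24 0.5497 0.25779 0.4582 0.8020
#> 2 ABCED 24 0.6726 0.14083 0.6788 0.8105
#> 3 EBCDA 24 1.5001 0.05865 1.4699 1.5575
#> 4 BACDE 24 0.7593 0.05819 0.7172 0.8163
```

Generated trajectories are closest (smallest median Fréchet distance) to
the never-experienced efficient tour ABCDE. Other experiments:
`intact_sequence`, `consolidation_fig5`, `tmaze_fig6` (reward size vs
distance trade-off), `reverse_fig8`, `shortcut_fig9` plus
`sweep_reverse_rate()` for the forward/reverse replay-rate U-shape. A thin
command-line wrapper lives in `inst/cli/snippetrc.R`.

## Acceptance script

`scripts/acceptance.R` re-runs the recombination experiment from scratch at
full scale (50 independently seeded 1000-unit reservoirs, 1000 snippets of
length 10 each, 5 noisy generations per reservoir) and writes the resulting
Kruskal-Wallis significance level to a JSON file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The run takes a few minutes on one CPU.

## Package layout

* `R/arena.R`, `R/scenarios.R` — arenas, feeders, idealized trajectories,
  reward signals, task fixtures
* `R/placecells.R` — place-field encoding and the spatial filter
* `R/replay.R` — reward propagation and snippet episode generation
* `R/reservoir.R` — the reservoir network and delta-rule training
  (inner loops in `src/core.cpp`)
* `R/generation.R` — autonomous / non-autonomous generation, random-walk
  populations, trajectory histograms
* `R/evaluation.R` — Fréchet distance, scores, group tests, state overlap
* `R/experiments.R` — the scripted, seeded experiments
* `vignettes/replay-consolidation-methods.Rmd` — model assumptions,
  parameter choices and known limitations
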