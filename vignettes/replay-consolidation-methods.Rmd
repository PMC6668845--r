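---
title: "Replay-driven consolidation of navigation sequences: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replay-driven consolidation of navigation sequences: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snippetrc)
```

## The model in one paragraph

A simulated rat forages among baited feeders and accumulates experienced
trajectories. Between trials, its hippocampus "replays" short windows of the
place-cell activity associated with those trajectories — snippets — with a
probability shaped by proximity to reward, in forward and reverse temporal
order. A prefrontal-cortex model — a reservoir network whose only plastic
part is a readout trained to predict the next place-cell activation — is
trained exclusively on these snippets. After training, a Bayesian decoder
(the *spatial filter*) converts each next-pattern prediction into a motor
step, closing the loop so the model walks on its own. Because reward-biased
replay over-represents the efficient sub-paths of inefficient experienced
tours, the reservoir consolidates those fragments into a trajectory close to
the efficient tour it never experienced — an approximate traveling-salesperson
behavior.

## Components and their assumptions

### Place-cell code

A uniform grid of `n_x` x `n_y` Gaussian place fields covers a 2 x 2 m
enclosure (default 16 x 16, so K = 256 cells). Cell k responds to location
s with

$$f_k(s) = \exp\!\left(-\frac{\|s - c_k\|^2}{w_k}\right), \qquad
  w_k = \frac{r_k^2}{-\log\Theta},$$

so that the rate equals the threshold $\Theta$ exactly at distance $r_k$
from the center. The field radius defaults to the grid spacing (0.125 m)
and $\Theta = 0.2$; neither value changes the qualitative behavior, both
are config-exposed. This is a firing-*rate* code — no spikes, no theta
phase, and the fields are given, not learned.

### Trajectories and reward

Trajectories are sampled at 20 points/m (one sample per simulated 5 ms
step). Idealized task trajectories are piecewise linear between feeders —
real rat paths are curved, but only the topology and relative path lengths
matter for the phenomena modeled here. The reward signal is deliberately
coarse: R(t) equals the feeder's reward magnitude at the sample where a
baited feeder is reached, and 0 elsewhere.

The five-feeder fixtures place 21 feeders on an Archimedean spiral in a
circle of radius 1.51 m and bait five of them. The baited spiral indices
are fixed constants chosen so that (i) all five feeders lie inside the
place-field coverage and (ii) the ABCDE tour is strictly shorter than the
three distractor tours ABCED, EBCDA, BACDE — the property that makes it
"the efficient tour". The tested property is the ordering of the four path
lengths, not any specific geometry.

### Replay with reward propagation

A per-time-index reward prediction V is initialized to small positive
noise ($U[0, \epsilon)$, $\epsilon = 0.01$) and updated by drawing snippet
windows (start index from the normalized likelihood P = V/sum(V), direction
reverse with probability $\beta_{learn}$) and applying, along each window,

$$V(\tau_i) \leftarrow \alpha\,(R(\tau_{i-1}) + \gamma V(\tau_{i-1}))
  + (1-\alpha)\,V(\tau_i).$$

Reverse windows move reward value backwards in time — the mechanism by
which value spreads from a reward into the approach path. Defaults
$\alpha = 0.1$, $\gamma = 0.9$, $\beta_{learn} = 0.5$ and a learning budget
of 10000 samples are stated in the package because the model behaves
robustly across a wide neighborhood of them; none is critical.

Generation then samples snippets i.i.d. from the final P under a second
budget (default 10000 samples at snippet length s = 10, i.e. 1000
snippets, matching the ecological estimate of replay volume in a 2-5
minute inter-trial interval). Windows are truncated at trajectory ends and
charge only their true length to the budget; the snippet window spans s
indices in both directions (the budget arithmetic 10000/10 = 1000 requires
equal-length forward and reverse windows). When several source
trajectories feed one episode, each snippet first picks a source with
probability proportional to that source's total V — a pragmatic reading of
"replay favors the more valuable experience" that the package flags as its
own choice; per-trajectory V is not carried across episodes.

### Reservoir and readout

The prefrontal model is an echo-state-style network of N = 1000
leaky-integrator tanh units. Input and recurrent weights are drawn once
from U[-1, 1]; recurrent weights are scaled by `k_scale / N` and the
diagonal is zeroed; only the readout matrix W_ro (initialized at zero) is
trained, with the tanh-readout Widrow-Hoff delta rule on mini-batches of
b = 32 steps, never mixing two snippets in one batch (the state is reset
to small uniform noise between snippets, standing in for the long
inter-replay interval). The update is gradient *descent* on the squared
readout error; the rule's sign is fixed by the requirement — verified in
the tests — that the batch MSE decreases on a repeated batch.

Three numerical choices deserve a note, because we calibrated them once
and they differ from naive guesses:

* **`k_scale` defaults to `sqrt(3N)`**, which puts the spectral radius of
  W_rec at ~1 (U[-1,1] entries have variance 1/3; the circular-law radius
  of the scaled matrix is `k_scale * sqrt(1/(3N))`). The echo property at
  this operating point is verified empirically in the tests.
* **`learning_rate` defaults to 0.005.** The delta rule is stable only for
  rates below roughly 2/||X_res||^2; with N = 1000 bounded states this is
  of order 0.005. Rates of 0.01 and above visibly saturate the readout
  (MSE *grows*); 0.005 converges in a single pass over 1000 snippets.
* **`leak_rate` defaults to 0.5.** At the 20 points/m sampling used here,
  leak rates below ~0.2 make the state too sluggish to track the input
  (next-step prediction degrades several-fold), while 0.5-0.8 perform
  equivalently; 0.5 keeps a few steps of temporal context, which the
  sequence-disambiguation behavior relies on.

### Spatial filter

The readout prediction is a noisy activation pattern; re-injecting it
directly diverges. Instead the most probable *reachable* next location is
selected: candidates are the current location plus a deterministic polar
lattice (8 radii x 23 angles) within 10 cm and ±110° of the current
heading, scored by the negative mean squared difference between the
prediction and each candidate's clean code, plus optional uniform score
noise U(0, m). The winning location is re-encoded noise-free and fed back.
Specifics the package fixes (the underlying probability model
P(s'|η, s) is not pinned down by the science):

* the similarity score (negative MSE) is maximized by the true location
  when the prediction is clean, and is cheap;
* the deterministic lattice makes the argmax reproducible; exact ties go
  to the lowest candidate index, and including the current location as
  candidate 1 makes the decoder idempotent on noiseless self-codes;
* with an undefined heading (coincident priming points, first step) the
  full circle is searched;
* `noise_m` is 0 wherever determinism is wanted and 2e-4 in the
  population experiments — about 1% of the typical spread of candidate
  scores around a trained prediction — enough to break degenerate ties
  and explore branches without destroying trained behavior.

### Generation and evaluation

Autonomous generation teacher-forces the first p steps (default p = s =
10; the network never saw longer coherent context during training) and
then runs closed-loop for a fixed number of steps. The packaged
experiments generate for the target sequence's duration plus an 8% buffer:
long overshoots otherwise dominate the Fréchet distance with
post-completion wander, which measures duration mismatch rather than path
shape (there is no reward-triggered stopping rule in the model).
Non-autonomous evaluation teacher-forces the *target's* codes at every
step and reports the per-step distance between the decoded prediction and
the true next point — pure next-step prediction quality, with no error
amplification.

Trajectory similarity uses the discrete Fréchet distance (dynamic
programming over all monotone couplings), computed on raw point sequences
without resampling; batches are summarized by score(X) = mean + population
standard deviation, and group contrasts use the Kruskal-Wallis rank test.

## What the synthetic data does and does not emulate

The generator reproduces the *task structure*: feeder layouts, visit
orders, piecewise-linear paths at the stated sampling resolution, and
coarse reward delivery. It does not emulate curved rat kinematics,
variable running speed, sensory noise, or any within-trial learning; a
green test therefore establishes that the replay + consolidation machinery
produces the claimed orderings and contrasts in this idealized world, not
that it fits any particular animal's data.

## The packaged experiments

* **Intact sequence**: uniform replay of the efficient tour; trained
  models track it, untrained models do not — the basic sanity contrast.
* **Consolidation**: reservoir states under snippet drive versus the
  intact sequence's state trajectory, compared in the top-2 PCA plane of
  the intact-sequence states with an overlap radius of 5% of the projected
  bounding-box diagonal, discarding the first 3 post-reset steps of each
  snippet. Two fractions are reported: the "snippet" direction (how many
  snippet states lie near the intact trajectory) and the "coverage"
  direction (how much of the intact trajectory is approached by some
  snippet state). Only coverage can grow
  with replay exposure — the per-snippet state distribution does not
  depend on how many snippets are replayed, so the snippet-direction
  fraction is flat in expectation — and the packaged experiment therefore
  evaluates nested episode prefixes (100 ⊂ 1000 ⊂ 10000 snippets of one
  replay process) and tests monotone growth of coverage. At the default
  radius, coverage saturates near 1 already at 100 snippets; tighter radii
  show the growth but the default is kept for comparability.
* **T-maze**: reward-modulated replay of ABC and ABD (shared prefix AB,
  C nearer than D). With equal rewards the replay mass and hence the
  generated behavior prefer the short arm; a 10x reward at D flips the
  preference — distance and reward magnitude trade off through the value
  propagation.
* **Recombination**: three inefficient tours, each containing one
  efficient sub-path; generations are closest to the never-experienced
  efficient tour. This is the package's headline quantitative result.
* **Reverse replay in generation** (see limitations below).
* **Shortcut**: two loops experienced in opposite directions; the full
  outer loop is evaluated non-autonomously. With forward-only replay the
  side experienced in the incongruent direction shows several-fold larger
  per-step errors; mixed forward/reverse replay (25-75%) minimizes the
  loop error, pure reverse mirrors pure forward — the characteristic
  U-shape, reproduced by `sweep_reverse_rate()` with paired seeds.

## Known limitations

* **Reverse replay during closed-loop generation does not help in this
  fixture world — it hurts.** In the reversed-source recombination
  setting, the forward training set already covers every target
  transition (the straight-segment fixtures share their efficient
  sub-paths geometrically), so reverse generation has no missing data to
  supply; instead it halves the consistent-direction training data and
  creates opposing-continuation conflicts at every location, which stall
  the spatial filter. The corresponding acceptance check is accordingly
  expected to fail, and is kept failing rather than weakened: in this
  package's stated world the benefit of reverse replay appears in the
  value-propagation phase (where it is large and tested) and in
  non-autonomous prediction (the shortcut U-shape), not in closed-loop
  generation. Curved, partially overlapping source trajectories — where
  forward coverage of the target is genuinely incomplete — are the regime
  where a closed-loop benefit would be expected.
* The model consumes idealized experience; it neither explores nor
  selects actions beyond the one-step spatial filter.
* Parallel replay within a ripple, ripple waveforms and replay timing are
  not modeled; a replay episode is just a budgeted bag of snippets.
* All results are population statements over seeds; single networks vary,
  and occasional failed generations (wrong branch taken, slow progress)
  are part of the reported distributions.
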