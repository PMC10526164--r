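---
title: "Methods: astrocyte-modulated synaptic short-term memory in a change-detection task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: astrocyte-modulated synaptic short-term memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astromem)
```

## The scientific question

Can short-term synaptic depression — rather than persistent recurrent
activity — carry the short-term memory needed to detect a change in a
stream of repeated images, and does astrocytic modulation of transmitter
release improve it? `astromem` implements three comparable models of the
memory stage and the behavioural task used to score them, so the
hypotheses can be compared head-to-head on identical simulated sessions:

* **astrocyte head** (`"stpanet"`): depressing synapses whose release
  probability is raised by a gliotransmitter variable (tripartite
  synapse);
* **depression-only head** (`"stpnet"`): the same synapses with the
  release probability pinned at its baseline;
* **recurrent head** (`"rnn"`): a small recurrent network holding memory
  in sustained activity, with no synaptic state.

## The synapse model

Each of the 64 input units carries an independent state $(x, y, u)$:
available resource fraction, gliotransmitter level and release
probability. With presynaptic drive $a(t) \ge 0$,

$$\frac{dx}{dt} = \frac{1 - x}{\tau_D} - u\,x\,a(t), \qquad
\frac{dy}{dt} = -\frac{y}{\tau_y} + \beta\,H_y(x), \qquad
u = u_0 + \frac{\Delta u_0}{1 + e^{-50\,(y - y_{thr})}},$$

with $H_y(x) = 1/(1 + e^{-20 (x - x_{thr})})$. The first equation is the
classical Tsodyks–Markram mean-field depression; the second accumulates
gliotransmitter while the resource is high; the third feeds it back as an
increase of release probability. Transmission at a step is the *effective
input* $e = u \cdot x \cdot a$.

Parameters and defaults (all times in *conventional units*; one unit is
one simulation step = one 250 ms image flash):

| parameter | default | meaning |
|---|---|---|
| `tau_d` | 6 | depression recovery time constant |
| `u0` | 0.23 | baseline release probability |
| `delta_u0` | 0.305 | astrocytic increment of release probability |
| `tau_y` | 1.8 | gliotransmitter relaxation time |
| `beta` | 0.4375 | gliotransmitter production gain |
| `x_thr`, `y_thr` | 0.5, 0.573 | sigmoid thresholds |
| slopes | 20, 50 | fixed sigmoid steepnesses |

So `u` is always confined to $(u_0, u_0 + \Delta u_0) = (0.23, 0.535)$,
saturating to the closed bounds in double precision.

### Numerical choices

* **Integration** is explicit Euler at `dt = 1` (the native step: one
  flash). The update order per step is fixed and documented for bit
  reproducibility: advance $x$ from $(x_t, u_t)$ and the drive, advance
  $y$ from $x_t$, then recompute $u$ from $y_{t+1}$. $x$ is clamped to
  $[0,1]$ after the step because a large drive at `dt = 1` can overshoot;
  clamping preserves the resource-fraction semantics.
* **Recorded states** at step $t$ are those *entering* the step, so the
  trajectory at $t$ depends only on drives before $t$, and
  `effective_series[t] = u[t] * x[t] * drive[t]`.
* **Discretization error.** `dt = 1` is coarse. Against a reference
  integration at `dt/100` the trajectory deviates by up to roughly 0.23
  in $x$, 0.36 in $y$ and 0.30 in $u$ under flash-train drive — the
  slope-50 sigmoid near `y_thr` amplifies small $y$ differences. The test
  suite therefore checks coarse agreement at a stated 0.4 tolerance; at
  `dt = 0.1` the tolerances are 0.1 on $x$ and $y$ and 0.2 on the
  sigmoid-amplified $u$; and refining the step must shrink the error. The model used throughout the package *is* the coarse map
  (that is how the memory stage is defined), the ODE comparison is a
  structural sanity check.
* **Periodic orbits, not fixed points.** Under the task's
  flash/gray/gray rhythm the flash-to-flash map of the coarse dynamics
  settles on a period-4 orbit rather than a fixed point: the steep
  release sigmoid plus the coarse step produce a period-doubled
  attractor. Tests detect the periodic attractor rather than assuming
  monotone convergence.
* **Equilibria** (`steady_state()`): eliminating $y$ and $u$ leaves the
  scalar equation $x = F(x)$ with $F$ nonincreasing, so the equilibrium
  is unique. Plain damped fixed-point iteration oscillates between the
  two branches of the slope-50 sigmoid for intermediate drives, so the
  root is found by bisection (tolerance 1e-12) instead.

### What the astrocyte changes

Repeated flashes deplete $x$ under both plasticity heads. In the
depression-only head the summed effective input decays monotonically to
a plateau. In the astrocyte head, $y$ crosses `y_thr` after the first
flashes, $u$ jumps from 0.23 toward 0.535, and the effective input is
partially restored (tail transmission about 35% higher in the default
world). Astrocytic modulation therefore acts as an activity-dependent
gain that counteracts depression — the mechanism credited with the
performance difference between the two heads.

```{r dynamics}
traj <- simulate_trace(rep(c(1, 0, 0), 20))
range(traj$u_series)          # astrocytic range of release probability
tail(traj$x_series[seq(1, 60, 3), 1], 4)   # depressed flash-step resource
```

## The change-detection task

A session is a 50,000 ms train of 250 ms image flashes separated by
500 ms of gray screen — 200 steps, one flash every 3 steps. One image
repeats for a uniformly drawn 4–11 flashes; then either the image
switches to a different uniformly drawn image (*Go* trial, label +1) or a
sham change leaves it unchanged (*Catch* trial, label −1). Each flash is
omitted independently with probability 0.05, except the flash immediately
before the event (the protocol constraint) and the event flash itself
(otherwise the trial would be unscorable — a package choice, documented
here). Sessions are encoded as a 200×64 matrix: the image's feature
vector at visible flash steps, zero rows elsewhere.

Open question resolved here: the session length could host several
events; one event per session is generated, because the trial-level
metrics treat each session as one labelled trial.

## Features

The 8 stimulus vectors come either from the FC-64 layer of a small
convolutional encoder (two same-padded convolution stages with 2×2
stride-2 max pooling, one fully connected stage, a rectified 64-unit
feature layer, and a class-score layer trained with softmax
cross-entropy under SGD) or from `synthetic_feature_bank()`. No
deep-learning framework is assumed: the encoder is implemented in base R
(im2col convolutions with hand-derived gradients, verified against
finite differences). The natural-image dataset used by the original
experiments is not bundled or downloaded; encoder defaults target small
synthetic image sets (16×16 blobs), and the synthetic bank is the
default feature source everywhere.

The synthetic bank mimics what matters downstream: nonnegative sparse
activations (marginal zero fraction exactly `sparsity`, default 0.8, as
observed for cortical responses), controllable pairwise similarity
(`overlap`, default 0.2), nonzero rows. What it does **not** emulate:
the similarity *structure* of natural images (all image pairs are
exchangeable), feature correlations, or amplitude heterogeneity across
images. A green test on synthetic banks therefore establishes the
machinery and qualitative mechanisms, not quantitative agreement with
image-derived numbers — see *Limitations*.

## Model heads and training

All heads share the 64-16-1 shape: rectified hidden layer, logistic
output. The plasticity heads transform the input through the synapse
bank ($e = u x a$, per unit) before the hidden layer; the recurrent head
uses $h_t = \tanh(W_{in} m_t + W_{rec} h_{t-1} + b)$. The synapse
variables are driven by the input alone and never depend on trainable
weights, so the question of whether gradients should flow through the
plasticity recursion is moot in this architecture — plasticity is a
per-step input gain, and gradients are exactly those of the downstream
network.

Training (`train_head()`) follows a per-epoch loop: generate a balanced
Go/Catch batch, forward, binary cross-entropy between the readout
probability (the output at the event step) and the binarized label,
backpropagate (through time, for the recurrent head), one Adam step,
then score the epoch d-prime on the training batch. Early stopping
mirrors behavioural training-to-criterion: the counter resets while
d′ < `dprime_threshold` (default 1.5, roughly the animals' level) and
training stops once d′ has held at criterion for `patience` (default 10)
consecutive epochs. Neither constant is printed in the source
experiments; both are exposed. Loss is computed at readout steps only,
because the trial metrics are defined per trial, not per time step.

## Behavioural metrics

* **d-prime** (`dprime()`): trials are split into blocks (round-robin
  within class so every block has both classes); the index is
  (mean block hit rate − mean block false-alarm rate) divided by the
  standard deviation of per-block differences, floored at 1e-6 so
  perfect detectors stay finite. This ratio form is the task's native
  index; the variability convention is not printed in the source
  material, so the per-block SD was chosen and is recorded. The
  classical Gaussian-inverse variant exists only as the clearly labelled
  `dprime_classical()`.
* **Response matrix** (`response_matrix()`): cell $(i, j)$ is the mean
  sampled response over trials where image $i$ was followed by image
  $j$; diagonal cells come only from Catch trials; empty cells stay `NA`.
* **Asymmetry index** (`asymmetry_index()`): the printed ratio form is
  degenerate (identical numerator and denominator), so the implemented
  default follows the prose — centre the matrix by its grand mean, split
  into symmetric and antisymmetric parts, and report
  $q = (\|A\|_F - \|S\|_F) / (\|S\|_F + \|A\|_F) \in [-1, 1]$. The
  convention is recorded in every result; `"norm-diff"` (no centring)
  and `"classic"` ($\|A\|_F / \|S\|_F$) are selectable.
* Responses are Bernoulli samples of the per-trial probabilities
  (reported metrics); an analytic mode (`sample = FALSE`) propagates
  expected responses for deterministic tests.

## Experiments

`run_experiment()` trains `n_runs` independent replicates of each head
and evaluates all heads of a run on the *same* freshly generated
evaluation sessions (paired comparison; sharpens contrasts without
biasing means), aggregating d-prime and asymmetry as mean ± SD. Every
random choice descends deterministically from the single experiment
seed, so a report is byte-reproducible.

## Limitations

* The quantitative reference values for the three models were obtained
  with image-trained feature banks. Offline, with synthetic banks at
  desk scale, trained models reliably show the qualitative patterns
  (depression, astrocytic compensation, early stopping, higher response
  to changes than repeats) but overshoot the reference d-prime band:
  with 10 evaluation blocks of 20 trials the per-block SD is ~0.15, so a
  model holding hit − false ≈ 0.5 scores d′ ≈ 3–4, and the run-to-run SD
  of the ratio is large (~1.2 at 5 runs), leaving the three-way ordering
  within noise. The acceptance suite asserts the reference bands anyway
  and the corresponding tests are expected to fail in this configuration;
  they document the gap rather than hiding it.
* The encoder is a functional miniature, not an image-classification
  model; it exists to produce feature banks.
* No spiking dynamics, no spatial/diffusive astrocyte coupling, no
  shared astrocyte pool (each input unit carries an independent
  $(x,y,u)$; nothing in the formulation defines a shared pool, and
  per-unit traces match the published dynamics figures).
* The drive scaling factor (`n_scale`, the "experiment count" multiplier
  of the presynaptic-activity definition) defaults to 1 with the feature
  activation as drive; its intended value is unconstrained by the source
  material.
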