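# astromem

Astrocyte-modulated short-term synaptic memory models for a simulated
visual change-detection task.

## The problem

In a change-detection task, a subject watches one image flash repeatedly
(250 ms on, 500 ms gray) and must respond when the image changes ("Go"
trials); sessions without a real change ("Catch" trials) measure false
alarms. Detecting the change requires a short-term memory of what was
just seen. Two competing accounts are implemented here:

* **memory in synapses** — repeated flashes depress the synapses driven
  by the repeated image (Tsodyks–Markram mean-field depression), so a
  novel image arrives through fresh, stronger synapses; optionally the
  release probability is boosted by astrocytic gliotransmission
  (the *tripartite synapse*), which partially restores transmission;
* **memory in activity** — a recurrent network sustains activity across
  the gray screen.

The package provides the synapse/astrocyte integrator, the task
simulator, a small image encoder plus a synthetic feature-bank
substitute, the three trainable model heads (astrocyte, depression-only,
recurrent), behavioural metrics, and an experiment orchestrator.

## The model in brief

Each of 64 input units carries an independent state (x, y, u):

    dx/dt = (1 - x)/tau_D - u * x * a(t)          resource (depression)
    dy/dt = -y/tau_y + beta * H(x)                gliotransmitter
    u(y)  = u0 + delta_u0 / (1 + exp(-50 (y - y_thr)))

with `H(x) = 1/(1 + exp(-20 (x - x_thr)))`, integrated by explicit Euler
at one step per 250 ms flash. Transmission is `u * x * a`. Defaults:
`tau_d = 6`, `u0 = 0.23`, `delta_u0 = 0.305`, `tau_y = 1.8`,
`beta = 0.4375`, `x_thr = 0.5`, `y_thr = 0.573`, so `u` lives in
[0.23, 0.535]. Performance is scored with a block-based d-prime
(hit rate minus false-alarm rate over the per-block variability), an
8×8 stimulus-transition response matrix, and a matrix asymmetry index.

## Worked example

```r
library(astromem)

# synapse dynamics under a flash/gray/gray drive
traj <- simulate_trace(rep(c(1, 0, 0), 20))
round(range(traj$u_series), 3)
#> [1] 0.230 0.535        # astrocytes sweep u across its full range

# a change-detection session and a trained astrocyte head
bank <- synthetic_feature_bank(seed = 1)   # 8 x 64 sparse features
head <- init_head(head_config("stpanet"), seed = 2)
fit  <- train_head(head, task_config(), bank, train_config(seed = 5))
fit
#> Training run (stpanet): 53 epochs, early_stop; final loss 0.2267, d' 4.330

# evaluate on fresh sessions
batch   <- make_batch(task_config(), 100, 100, bank, seed = 77)
outcome <- evaluate_head(fit$head, batch, seed = 9)
dprime(outcome)
#> d' = 3.930  (hit 0.840, false alarm 0.260, sigma 0.1476; 100 Go / 100 Catch)
rm_ <- response_matrix(outcome, 8)
rm_
#> Response matrix: 8 x 8 (9 empty cells)
#>   mean off-diagonal 0.831, mean diagonal 0.251
asymmetry_index(rm_$probs)
#> Asymmetry index q = 0.0483 (centered-norm-diff)
```

Reading the numbers: training stopped early once d-prime held above the
1.5 criterion for 10 consecutive epochs. On fresh sessions the model
responds to 84% of real changes and 26% of sham changes; the response
matrix shows the same contrast per image transition (off-diagonal 0.83
vs diagonal 0.25), i.e. the depressing synapses remember the repeated
image. The asymmetry index summarizes how unevenly transitions are
detected.

A full three-model comparison (takes a few minutes):

```r
report <- run_experiment(experiment_config(n_runs = 5, seed = 42))
report$summary   # per-model mean ± sd of d-prime and asymmetry
```

## Command line

```sh
Rscript inst/cli/astromem.R simulate-synapse --steps 60 --out out/
Rscript inst/cli/astromem.R make-features --seed 4 --out out/
Rscript inst/cli/astromem.R train-head --model stpanet --out out/
Rscript inst/cli/astromem.R compare --n-runs 5 --out out/
```

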