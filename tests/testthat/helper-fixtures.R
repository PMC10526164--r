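# Shared fixtures and independent oracles.

paper_params <- function() synapse_params()

# Small task for fast tests: 48 steps, 16 flashes, 4 images.
small_task <- function(omission_rate = 0.05) {
  task_config(length_ms = 12000, time_step_ms = 250, gray_steps = 2,
              n_images = 4, omission_rate = omission_rate,
              min_repeats = 2, max_repeats = 6)
}

small_bank <- function(seed = 11) {
  synthetic_feature_bank(n_images = 4, dim = 64, sparsity = 0.7,
                         overlap = 0.2, seed = seed)
}

# An easy, fully separable world: orthogonal block features, no omissions.
orthogonal_bank <- function(n_images = 4, dim = 64) {
  v <- matrix(0, n_images, dim)
  width <- dim %/% n_images
  for (i in seq_len(n_images)) {
    v[i, (i - 1) * width + seq_len(width)] <- 1
  }
  feature_bank(v, "synthetic")
}

# Independent reference integrator for the synapse ODEs: plain Euler at a
# much finer step, written without the package's update machinery. The
# coarse-step drive is held constant within each coarse step.
ref_integrate <- function(drive, params, dt = 1, refine = 100L,
                          x0 = 1, y0 = 0) {
  sub <- dt / refine
  x <- x0; y <- y0
  xs <- ys <- us <- numeric(length(drive))
  for (t in seq_along(drive)) {
    xs[t] <- x; ys[t] <- y
    us[t] <- params$u0 + params$delta_u0 /
      (1 + exp(-params$slope_y * (y - params$y_thr)))
    for (s in seq_len(refine)) {
      u <- params$u0 + params$delta_u0 /
        (1 + exp(-params$slope_y * (y - params$y_thr)))
      hy <- 1 / (1 + exp(-params$slope_x * (x - params$x_thr)))
      dx <- (1 - x) / params$tau_d - u * x * drive[t]
      dy <- -y / params$tau_y + params$beta * hy
      x <- min(max(x + sub * dx, 0), 1)
      y <- max(y + sub * dy, 0)
    }
  }
  list(x = xs, y = ys, u = us)
}

# Plain feedforward readout head evaluated directly (oracle for the
# plasticity-free limits of the model forwards).
mlp_probs_oracle <- function(m, wts) {
  h <- pmax(sweep(m %*% wts$w1, 2, wts$b1, `+`), 0)
  as.vector(1 / (1 + exp(-(h %*% wts$w2 + wts$b2))))
}

# Finite-difference gradient of a scalar loss over one weight array.
fd_grad <- function(loss_fn, wts, nm, eps = 1e-6) {
  g <- wts[[nm]] * 0
  for (i in seq_along(g)) {
    wp <- wts; wp[[nm]][i] <- wp[[nm]][i] + eps
    wm <- wts; wm[[nm]][i] <- wm[[nm]][i] - eps
    g[i] <- (loss_fn(wp) - loss_fn(wm)) / (2 * eps)
  }
  g
}
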