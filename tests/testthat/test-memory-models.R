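test_that("astrocyte head reduces bit-exactly to the depression-only head", {
  # the central reduction contract: delta_u0 = 0 and beta = 0 silence the
  # astrocyte pathway entirely
  p0 <- synapse_params(delta_u0 = 0, beta = 0)
  hc <- head_config("stpanet", synapse = p0)
  head <- init_head(hc, seed = 3)
  bank <- small_bank()
  m <- encode_session(generate_session(small_task(), 1, seed = 2), bank)
  fa <- stpanet_forward(m, head)
  fs <- stpnet_forward(m, head)
  expect_identical(fa$prob, fs$prob)
  expect_identical(fa$hidden, fs$hidden)
  expect_identical(fa$effective, fs$effective)
})

test_that("all-zero input yields a constant bias-driven output", {
  m <- matrix(0, 30, 64)
  for (kind in c("stpanet", "stpnet")) {
    head <- init_head(head_config(kind), seed = 4)
    fw <- forward_model(head, m)
    expect_equal(length(unique(fw$prob)), 1L)
    expect_equal(fw$prob[1],
                 as.vector(plogis(pmax(head$weights$b1, 0) %*%
                                    head$weights$w2 + head$weights$b2)))
  }
  # rnn with zero input, zero initial hidden and zero biases -> logistic(0)
  hr <- init_head(head_config("rnn"), seed = 4)
  hr$weights$b1[] <- 0
  hr$weights$b2[] <- 0
  fr <- rnn_forward(m, hr)
  expect_equal(fr$prob, rep(0.5, 30))
})

test_that("repeated flashes depress transmission; astrocytes partly compensate", {
  bank <- small_bank()
  # one image flashed repeatedly with the task's flash/gray rhythm
  m <- matrix(0, 90, 64)
  flash_steps <- seq(1, 90, by = 3)
  m[flash_steps, ] <- matrix(bank$vectors[1, ], length(flash_steps), 64,
                             byrow = TRUE)
  head <- init_head(head_config("stpanet"), seed = 1)
  fa <- stpanet_forward(m, head)
  fn <- stpnet_forward(m, head)
  # depression-only: summed effective input is non-increasing to a plateau
  en <- rowSums(fn$effective[flash_steps, ])
  expect_true(all(diff(en) <= 1e-8))
  expect_lt(abs(en[length(en)] - en[length(en) - 1]), 1e-3 * en[1])
  expect_lt(en[length(en)], en[1])
  # both heads deplete the resource at every post-onset flash (checked on
  # a unit that actually receives drive)
  unit <- which(bank$vectors[1, ] > 0)[1]
  for (fw in list(fa, fn)) {
    x_flash <- fw$trajectory$x_series[flash_steps, unit]
    expect_true(all(x_flash[-1] < x_flash[1]))
  }
  # astrocytic modulation raises u and partly offsets the depression
  ea <- rowSums(fa$effective[flash_steps, ])
  n_tail <- 8
  expect_gt(mean(utils::tail(ea, n_tail)), mean(utils::tail(en, n_tail)))
  expect_gt(max(fa$trajectory$u_series), max(fn$trajectory$u_series))
})

test_that("negative input is rejected by the plasticity heads only", {
  head <- init_head(head_config("stpanet"), seed = 1)
  m <- matrix(-1, 5, 64)
  expect_error(stpanet_forward(m, head), "nonnegative")
  hr <- init_head(head_config("rnn"), seed = 1)
  expect_silent(rnn_forward(m, hr))
})

test_that("depression-only head approaches a plain feedforward net in the no-depression limit", {
  # u0 = 1 with near-instant recovery (tau_d -> 0) keeps x ~ 1 at every
  # flash, so the effective input equals the raw input
  p_lim <- synapse_params(tau_d = 1e-3, u0 = 1, delta_u0 = 0)
  head <- init_head(head_config("stpnet", synapse = p_lim), seed = 5)
  bank <- small_bank()
  m <- encode_session(generate_session(small_task(), 1, seed = 8), bank)
  fw <- stpnet_forward(m, head)
  oracle <- mlp_probs_oracle(m, head$weights)
  expect_equal(fw$prob, oracle, tolerance = 1e-6)
})

test_that("depression trajectory inside the head matches the bare integrator", {
  bank <- small_bank()
  head <- init_head(head_config("stpnet"), seed = 2)
  m <- encode_session(generate_session(small_task(), -1, seed = 3), bank)
  fw <- stpnet_forward(m, head)
  p0 <- synapse_params(delta_u0 = 0, beta = 0)
  traj <- simulate_trace(m, p0)
  expect_identical(fw$trajectory$x_series, traj$x_series)
})

test_that("recurrent head limits behave as documented", {
  hr <- init_head(head_config("rnn"), seed = 6)
  m <- matrix(abs(rnorm(20 * 64, sd = 0.5)), 20, 64)
  # W_rec = 0 -> per-step feedforward network with tanh hidden
  hr0 <- hr
  hr0$weights$w_rec[] <- 0
  fw <- rnn_forward(m, hr0)
  h_ff <- tanh(sweep(m %*% hr0$weights$w1, 2, hr0$weights$b1, `+`))
  expect_equal(fw$prob,
               as.vector(plogis(h_ff %*% hr0$weights$w2 + hr0$weights$b2)),
               tolerance = 1e-12)
  # spectral radius near 1 sustains activity after a single flash
  hp <- hr
  hp$weights$w_rec <- diag(0.95, 16)
  hp$weights$b1[] <- 0
  m1 <- matrix(0, 25, 64)
  m1[1, ] <- 1
  fp <- rnn_forward(m1, hp)
  norms <- sqrt(rowSums(fp$hidden^2))
  expect_gt(norms[20], 0.2 * norms[2])   # persistence
  hp0 <- hp
  hp0$weights$w_rec[] <- 0
  f0 <- rnn_forward(m1, hp0)
  expect_lt(sqrt(sum(f0$hidden[20, ]^2)), 1e-12)  # no recurrence, no memory
})

test_that("readout extracts the event-step probability", {
  prob <- rep(0.7, 50)
  s <- generate_session(small_task(), 1, seed = 1)
  expect_equal(readout(prob, s), 0.7)
  prob2 <- seq(0, 1, length.out = 50)
  expect_equal(readout(prob2, 10L), prob2[10])
  expect_equal(readout(prob2, 10L, window = 1), prob2[10])
  expect_gte(readout(prob2, 10L, window = 5), prob2[10])  # max over window
  expect_error(readout(prob2, 51L), "outside")
  expect_error(readout(prob2, 10L, window = 0), "window")
})

test_that("backpropagated gradients match finite differences", {
  set.seed(1)
  wts <- list(w1 = matrix(rnorm(8 * 4, 0, 0.5), 8, 4),
              b1 = rnorm(4, 0, 0.1),
              w2 = matrix(rnorm(4), 4, 1), b2 = rnorm(1))
  x <- matrix(abs(rnorm(5 * 8)), 5, 8)
  y <- c(1, 0, 1, 0, 1)
  fg <- astromem:::mlp_loss_grad(wts, x, y)
  for (nm in names(wts)) {
    gn <- fd_grad(function(w) astromem:::mlp_loss_grad(w, x, y)$loss,
                  wts, nm)
    expect_lt(max(abs(gn - fg$grads[[nm]])) / max(max(abs(gn)), 1e-8), 1e-4)
  }
  # recurrent head: gradients through time
  wr <- list(w1 = matrix(rnorm(6 * 3, 0, 0.5), 6, 3), b1 = rnorm(3, 0, 0.1),
             w2 = matrix(rnorm(3), 3, 1), b2 = rnorm(1),
             w_rec = matrix(rnorm(9, 0, 0.3), 3, 3))
  si <- lapply(1:7, function(t) matrix(rnorm(4 * 6), 4, 6))
  rs <- c(3L, 5L, 7L, 2L)
  yy <- c(1, 0, 1, 0)
  fg2 <- astromem:::rnn_loss_grad(wr, si, rs, yy)
  for (nm in names(wr)) {
    gn <- fd_grad(function(w) astromem:::rnn_loss_grad(w, si, rs, yy)$loss,
                  wr, nm)
    expect_lt(max(abs(gn - fg2$grads[[nm]])) / max(max(abs(gn)), 1e-8), 1e-4)
  }
})

test_that("training respects the epoch budget and early-stop bookkeeping", {
  cfg <- small_task()
  bank <- small_bank()
  head <- init_head(head_config("stpanet"), seed = 1)
  # infinite threshold -> early stopping never engages
  tc <- train_config(n_epochs = 4, dprime_threshold = Inf, n_go = 8,
                     n_catch = 8, n_blocks = 2, seed = 2)
  tr <- train_head(head, cfg, bank, tc)
  expect_equal(tr$epochs_run, 4L)
  expect_identical(tr$stop_reason, "max_epochs")
  expect_length(tr$loss, 4L)
  expect_length(tr$dprime, 4L)
  # fixed seed -> identical result
  tr2 <- train_head(head, cfg, bank, tc)
  expect_identical(tr, tr2)
})

test_that("a separable toy task is learned with decreasing loss and early stop", {
  cfg <- small_task(omission_rate = 0)
  bank <- orthogonal_bank()
  head <- init_head(head_config("stpanet"), seed = 1)
  tc <- train_config(n_epochs = 120, dprime_threshold = 1.5, patience = 3,
                     n_go = 12, n_catch = 12, n_blocks = 2,
                     batch_mode = "fixed", lr = 0.02, seed = 4)
  tr <- train_head(head, cfg, bank, tc)
  expect_identical(tr$stop_reason, "early_stop")
  # deterministic fixed-batch loss decreases over the early epochs
  expect_true(all(diff(tr$loss[1:10]) < 0))
  expect_lt(tr$loss[tr$epochs_run], tr$loss[1])
})

test_that("training curves export to CSV", {
  cfg <- small_task()
  head <- init_head(head_config("rnn"), seed = 1)
  tr <- train_head(head, cfg, small_bank(),
                   train_config(n_epochs = 2, dprime_threshold = Inf,
                                n_go = 6, n_catch = 6, n_blocks = 2,
                                seed = 1))
  f <- withr::local_tempfile(fileext = ".csv")
  df <- train_result_to_df(tr, f)
  expect_named(utils::read.csv(f), c("epoch", "loss", "dprime"))
})
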