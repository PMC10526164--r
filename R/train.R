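#' Training configuration for the memory-model heads
#'
#' One epoch generates (or reuses) a balanced Go/Catch batch, runs the
#' forward pass, computes binary cross-entropy between the per-trial
#' readout probability and the binarized label (Go -> 1, Catch -> 0),
#' backpropagates and applies one adaptive-moment (Adam) update, then
#' scores the epoch d-prime on the training batch. The early-stopping
#' counter resets while d-prime is below `dprime_threshold`, increments
#' once it reaches the threshold, and training stops when it reaches
#' `patience` — i.e. performance must be held at the target level for
#' `patience` consecutive epochs.
#'
#' @param n_epochs Maximum number of epochs.
#' @param lr,beta1,beta2,eps Adam settings.
#' @param dprime_threshold Early-stop performance target (default 1.5;
#'   `Inf` disables early stopping).
#' @param patience Consecutive at-threshold epochs required to stop
#'   (default 10).
#' @param n_go,n_catch Trials per training batch.
#' @param n_blocks Blocks used for the epoch d-prime (each block must
#'   contain both trial classes).
#' @param batch_mode `"fresh"` regenerates the batch every epoch (the
#'   default, matching the train-batch-per-epoch loop); `"fixed"` reuses
#'   one batch, giving a deterministic loss curve.
#' @param seed Integer seed; fully determines the training run.
#' @return An object of class `train_config`.
#' @export
train_config <- function(n_epochs = 200L, lr = 0.01, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8,
                         dprime_threshold = 1.5, patience = 10L,
                         n_go = 32L, n_catch = 32L, n_blocks = 4L,
                         batch_mode = c("fresh", "fixed"), seed = 1L) {
  batch_mode <- match.arg(batch_mode)
  if (patience < 1L) stop_param("patience must be >= 1")
  if (n_go < 1L || n_catch < 1L) stop_param("need Go and Catch trials")
  if (n_blocks < 2L || n_blocks > min(n_go, n_catch)) {
    stop_param("n_blocks must be in 2..min(n_go, n_catch)")
  }
  if (is.na(dprime_threshold)) stop_param("dprime_threshold must be numeric")
  structure(
    list(n_epochs = as.integer(n_epochs), lr = lr, beta1 = beta1,
         beta2 = beta2, eps = eps, dprime_threshold = dprime_threshold,
         patience = as.integer(patience), n_go = as.integer(n_go),
         n_catch = as.integer(n_catch), n_blocks = as.integer(n_blocks),
         batch_mode = batch_mode, seed = as.integer(seed)),
    class = "train_config"
  )
}

# Effective inputs at each trial's readout step for the plasticity heads.
# Sessions share the synapse integrator, so the whole batch is simulated as
# one wide drive matrix (units are independent).
batch_effective_readout <- function(head, batch, params) {
  d <- head$config$input_dim
  n <- length(batch$inputs)
  big <- do.call(cbind, batch$inputs)
  traj <- simulate_trace(head$config$n_scale * big, params)
  x <- matrix(0, n, d)
  for (i in seq_len(n)) {
    x[i, ] <- traj$effective_series[batch$readout_steps[i],
                                    (i - 1L) * d + seq_len(d)]
  }
  x
}

# Loss and gradients of the readout MLP (plasticity heads). The synapse
# variables depend only on the input drive, never on the weights, so the
# trainable path is input -> hidden -> output at the readout step.
mlp_loss_grad <- function(wts, x, y01) {
  n <- nrow(x)
  z1 <- sweep(x %*% wts$w1, 2L, wts$b1, `+`)
  h <- relu(z1)
  z2 <- as.vector(h %*% wts$w2) + wts$b2
  p <- logistic(z2)
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  loss <- -mean(y01 * log(pc) + (1 - y01) * log(1 - pc))
  dz2 <- matrix((p - y01) / n, ncol = 1L)
  dh <- dz2 %*% t(wts$w2)
  dz1 <- dh * (z1 > 0)
  list(loss = loss, prob = p,
       grads = list(w1 = crossprod(x, dz1), b1 = colSums(dz1),
                    w2 = crossprod(h, dz2), b2 = sum(dz2)))
}

# Batched RNN forward: step_inputs[[t]] is the n x input_dim matrix at
# step t; returns hidden array (T, n, hidden_dim).
rnn_forward_batch <- function(wts, step_inputs, n, nh) {
  t_steps <- length(step_inputs)
  hs <- array(NA_real_, c(t_steps, n, nh))
  h <- matrix(0, n, nh)
  for (t in seq_len(t_steps)) {
    h <- tanh(sweep(step_inputs[[t]] %*% wts$w1 + h %*% wts$w_rec,
                    2L, wts$b1, `+`))
    hs[t, , ] <- h
  }
  hs
}

# Loss and gradients of the recurrent head via backpropagation through
# time, with the loss injected at each trial's readout step.
rnn_loss_grad <- function(wts, step_inputs, readout_steps, y01) {
  n <- length(readout_steps)
  nh <- ncol(wts$w_rec)
  t_steps <- length(step_inputs)
  hs <- rnn_forward_batch(wts, step_inputs, n, nh)
  h_read <- matrix(NA_real_, n, nh)
  for (i in seq_len(n)) h_read[i, ] <- hs[readout_steps[i], i, ]
  z2 <- as.vector(h_read %*% wts$w2) + wts$b2
  p <- logistic(z2)
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  loss <- -mean(y01 * log(pc) + (1 - y01) * log(1 - pc))
  dz2 <- (p - y01) / n
  g <- list(w1 = wts$w1 * 0, b1 = numeric(nh), w2 = crossprod(h_read,
                                                              matrix(dz2)),
            b2 = sum(dz2), w_rec = wts$w_rec * 0)
  carry <- matrix(0, n, nh)  # dL/da_{t+1} propagated backwards
  for (t in rev(seq_len(t_steps))) {
    ht <- matrix(hs[t, , ], n, nh)
    dh <- carry %*% t(wts$w_rec)
    at_readout <- which(readout_steps == t)
    if (length(at_readout)) {
      dh[at_readout, ] <- dh[at_readout, , drop = FALSE] +
        outer(dz2[at_readout], as.vector(wts$w2))
    }
    ga <- dh * (1 - ht^2)
    g$w1 <- g$w1 + crossprod(step_inputs[[t]], ga)
    g$b1 <- g$b1 + colSums(ga)
    h_prev <- if (t > 1L) matrix(hs[t - 1L, , ], n, nh) else matrix(0, n, nh)
    g$w_rec <- g$w_rec + crossprod(h_prev, ga)
    carry <- ga
  }
  list(loss = loss, prob = p, grads = g)
}

adam_init <- function(wts) {
  list(m = lapply(wts, function(w) w * 0),
       v = lapply(wts, function(w) w * 0), t = 0L)
}

adam_update <- function(wts, grads, state, cfg) {
  state$t <- state$t + 1L
  corr1 <- 1 - cfg$beta1^state$t
  corr2 <- 1 - cfg$beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * grads[[nm]]
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] +
      (1 - cfg$beta2) * grads[[nm]]^2
    wts[[nm]] <- wts[[nm]] - cfg$lr * (state$m[[nm]] / corr1) /
      (sqrt(state$v[[nm]] / corr2) + cfg$eps)
  }
  list(wts = wts, state = state)
}

# Per-trial readout probabilities for a whole batch under the current
# weights (no gradients). Used for evaluation.
batch_trial_probs <- function(head, batch, window = 1L) {
  kind <- head$config$model_kind
  n <- length(batch$inputs)
  wts <- head$weights
  if (kind %in% c("stpanet", "stpnet")) {
    params <- if (kind == "stpnet") {
      depression_only_params(head$config$synapse)
    } else {
      head$config$synapse
    }
    d <- head$config$input_dim
    big <- do.call(cbind, batch$inputs)
    traj <- simulate_trace(head$config$n_scale * big, params)
    vapply(seq_len(n), function(i) {
      cols <- (i - 1L) * d + seq_len(d)
      steps <- batch$readout_steps[i]:
        min(batch$readout_steps[i] + window - 1L, nrow(big))
      e <- traj$effective_series[steps, cols, drop = FALSE]
      h <- relu(sweep(e %*% wts$w1, 2L, wts$b1, `+`))
      max(logistic(as.vector(h %*% wts$w2) + wts$b2))
    }, numeric(1))
  } else {
    nh <- head$config$hidden_dim
    step_inputs <- batch_step_inputs(batch)
    hs <- rnn_forward_batch(wts, step_inputs, n, nh)
    vapply(seq_len(n), function(i) {
      steps <- batch$readout_steps[i]:
        min(batch$readout_steps[i] + window - 1L, length(step_inputs))
      h <- matrix(hs[steps, i, ], length(steps), nh)
      max(logistic(as.vector(h %*% wts$w2) + wts$b2))
    }, numeric(1))
  }
}

batch_step_inputs <- function(batch) {
  t_steps <- nrow(batch$inputs[[1]])
  lapply(seq_len(t_steps), function(t) {
    do.call(rbind, lapply(batch$inputs, function(m) m[t, ]))
  })
}

#' Train a memory-model head on the change-detection task
#'
#' Runs the epoch loop described in [train_config()] for any of the three
#' head kinds, with loss computed at the per-trial readout step only.
#'
#' @param head A [init_head()] result.
#' @param task_cfg A [task_config()].
#' @param bank A [feature_bank()].
#' @param cfg A [train_config()].
#' @return An object of class `train_result`: the trained `head`, per-epoch
#'   `loss` and `dprime` series, `epochs_run` and `stop_reason`
#'   (`"max_epochs"` or `"early_stop"`).
#' @export
train_head <- function(head, task_cfg, bank, cfg = train_config()) {
  stopifnot(inherits(head, "model_head"), inherits(cfg, "train_config"))
  kind <- head$config$model_kind
  with_seed(cfg$seed, {
    wts <- head$weights
    adam <- adam_init(wts)
    loss_series <- dprime_series <- numeric(0)
    wait_count <- 0L
    stop_reason <- "max_epochs"
    fixed_batch <- if (cfg$batch_mode == "fixed") {
      make_batch(task_cfg, cfg$n_go, cfg$n_catch, bank,
                 seed = derive_seed(cfg$seed, 0L))
    } else {
      NULL
    }
    epochs_run <- 0L
    for (epoch in seq_len(cfg$n_epochs)) {
      batch <- fixed_batch %||%
        make_batch(task_cfg, cfg$n_go, cfg$n_catch, bank,
                   seed = derive_seed(cfg$seed, epoch))
      y01 <- as.numeric(batch$labels == 1L)
      if (kind %in% c("stpanet", "stpnet")) {
        params <- if (kind == "stpnet") {
          depression_only_params(head$config$synapse)
        } else {
          head$config$synapse
        }
        x <- batch_effective_readout(
          structure(list(config = head$config, weights = wts),
                    class = "model_head"),
          batch, params)
        fg <- mlp_loss_grad(wts, x, y01)
      } else {
        fg <- rnn_loss_grad(wts, batch_step_inputs(batch),
                            batch$readout_steps, y01)
      }
      if (!is.finite(fg$loss)) {
        stop("non-finite loss at epoch ", epoch, " (", kind,
             "); last finite loss: ",
             if (length(loss_series)) utils::tail(loss_series, 1) else "none")
      }
      upd <- adam_update(wts, fg$grads, adam, cfg)
      wts <- upd$wts
      adam <- upd$state
      outcome <- detection_outcome(
        probs = fg$prob, labels = batch$labels,
        block_ids = block_assignment(batch$labels, cfg$n_blocks),
        pre_images = vapply(batch$sessions, `[[`, integer(1), "pre_image"),
        post_images = vapply(batch$sessions, `[[`, integer(1), "post_image"))
      dp <- dprime(outcome)$dprime
      loss_series <- c(loss_series, fg$loss)
      dprime_series <- c(dprime_series, dp)
      epochs_run <- epoch
      if (dp < cfg$dprime_threshold) {
        wait_count <- 0L
      } else {
        wait_count <- wait_count + 1L
        if (wait_count >= cfg$patience) {
          stop_reason <- "early_stop"
          break
        }
      }
    }
    trained <- structure(list(config = head$config, weights = wts),
                         class = "model_head")
    structure(
      list(head = trained, loss = loss_series, dprime = dprime_series,
           epochs_run = epochs_run, stop_reason = stop_reason,
           train_config = cfg),
      class = "train_result"
    )
  })
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("Training run (%s): %d epochs, %s; final loss %.4f, d' %.3f\n",
              x$head$config$model_kind, x$epochs_run, x$stop_reason,
              utils::tail(x$loss, 1), utils::tail(x$dprime, 1)))
  invisible(x)
}

#' Export a training curve as a data frame / CSV
#'
#' @param result A [train_head()] result.
#' @param file Optional CSV path.
#' @return Data frame with columns epoch, loss, dprime.
#' @export
train_result_to_df <- function(result, file = NULL) {
  stopifnot(inherits(result, "train_result"))
  df <- data.frame(epoch = seq_len(result$epochs_run),
                   loss = result$loss, dprime = result$dprime)
  if (!is.null(file)) {
    utils::write.csv(df, file, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Evaluate a trained head on a batch of sessions
#'
#' Computes per-trial readout probabilities, samples binary responses and
#' assembles a [detection_outcome()] ready for d-prime and
#' response-matrix computation.
#'
#' @param head A `model_head`.
#' @param batch A [make_batch()] result.
#' @param n_blocks Number of blocks for d-prime variance estimation.
#' @param window Readout window in steps (default 1).
#' @param sample Draw Bernoulli responses (default). With `FALSE` the
#'   outcome carries expected responses (`predictions = probs`), an
#'   analytic mode for deterministic tests.
#' @param seed Optional seed for the response draw.
#' @return A [detection_outcome()].
#' @export
evaluate_head <- function(head, batch, n_blocks = 10L, window = 1L,
                          sample = TRUE, seed = NULL) {
  probs <- batch_trial_probs(head, batch, window)
  preds <- if (sample) {
    with_seed(seed, sample_responses(probs))
  } else {
    probs
  }
  detection_outcome(
    probs = probs, labels = batch$labels,
    predictions = preds,
    block_ids = block_assignment(batch$labels, n_blocks),
    pre_images = vapply(batch$sessions, `[[`, integer(1), "pre_image"),
    post_images = vapply(batch$sessions, `[[`, integer(1), "post_image"))
}
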