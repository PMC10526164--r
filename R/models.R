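#' Configuration of a memory-model head
#'
#' All three comparable heads share the 64-16-1 shape: an input layer the
#' width of the feature bank, a hidden layer of 16 rectified units and one
#' logistic output unit giving the per-step response probability. The two
#' plasticity heads (`"stpanet"`, `"stpnet"`) pass the input through a bank
#' of depressing synapses — with and without astrocytic modulation of the
#' release probability — before the hidden layer; the `"rnn"` head instead
#' carries a recurrent hidden state.
#'
#' @param model_kind One of `"stpanet"`, `"stpnet"`, `"rnn"`.
#' @param input_dim,hidden_dim,output_dim Layer widths; defaults 64/16/1.
#' @param synapse A [synapse_params()] object (plasticity heads only).
#' @param n_scale Scaling factor applied to the input drive before the
#'   synapse bank (the experiment-count multiplier of the presynaptic
#'   activity definition; default 1).
#' @return An object of class `head_config`.
#' @export
head_config <- function(model_kind = c("stpanet", "stpnet", "rnn"),
                        input_dim = 64L, hidden_dim = 16L, output_dim = 1L,
                        synapse = synapse_params(), n_scale = 1) {
  model_kind <- match.arg(model_kind)
  if (output_dim != 1L) stop_param("output_dim is fixed at 1")
  check_scalar(n_scale, "n_scale", lower = 0, strict_lower = TRUE)
  structure(
    list(model_kind = model_kind, input_dim = as.integer(input_dim),
         hidden_dim = as.integer(hidden_dim), output_dim = 1L,
         synapse = synapse, n_scale = n_scale),
    class = "head_config"
  )
}

#' Initialize the weights of a model head
#'
#' Glorot-uniform initialization; the RNN additionally gets a recurrent
#' matrix scaled to spectral radius well below 1 for stability.
#'
#' @param config A [head_config()].
#' @param seed Optional integer seed.
#' @return An object of class `model_head` holding the config and weights
#'   `w1` (input x hidden), `b1`, `w2` (hidden x 1), `b2`, and `w_rec`
#'   (hidden x hidden, RNN only).
#' @export
init_head <- function(config, seed = NULL) {
  stopifnot(inherits(config, "head_config"))
  with_seed(seed, {
    glorot <- function(n_in, n_out) {
      lim <- sqrt(6 / (n_in + n_out))
      matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
    }
    wts <- list(
      w1 = glorot(config$input_dim, config$hidden_dim),
      b1 = numeric(config$hidden_dim),
      w2 = glorot(config$hidden_dim, 1L),
      b2 = numeric(1L)
    )
    if (config$model_kind == "rnn") {
      wts$w_rec <- glorot(config$hidden_dim, config$hidden_dim) * 0.5
    }
    structure(list(config = config, weights = wts), class = "model_head")
  })
}

#' @export
print.model_head <- function(x, ...) {
  cat(sprintf("%s head: %d -> %d -> 1\n", toupper(x$config$model_kind),
              x$config$input_dim, x$config$hidden_dim))
  invisible(x)
}

# Depression-only parameter set: delta_u0 = 0 pins u to u0 exactly and
# beta = 0 keeps y at 0, so the same integrator serves both plasticity heads.
depression_only_params <- function(params) {
  synapse_params(tau_d = params$tau_d, u0 = params$u0, delta_u0 = 0,
                 tau_y = params$tau_y, beta = 0, x_thr = params$x_thr,
                 y_thr = params$y_thr, slope_x = params$slope_x,
                 slope_y = params$slope_y)
}

plasticity_forward <- function(m, head, params, initial) {
  if (any(m < 0)) stop_param("plasticity heads require nonnegative input")
  drive <- head$config$n_scale * m
  traj <- simulate_trace(drive, params, initial)
  e <- traj$effective_series
  w <- head$weights
  h <- relu(sweep(e %*% w$w1, 2L, w$b1, `+`))
  prob <- as.vector(logistic(h %*% w$w2 + w$b2))
  structure(list(prob = prob, hidden = h, effective = e, trajectory = traj,
                 model_kind = head$config$model_kind),
            class = "model_forward")
}

#' Forward pass of the astrocyte-modulated plasticity head
#'
#' Each of the 64 input units carries an independent depressing synapse
#' with astrocytic release-probability modulation. At every step the
#' effective input is `u * x * input`, the synapse state advances by one
#' Euler step, and the effective vector feeds the rectified hidden layer
#' and logistic output. The synapse variables are input-driven modulating
#' signals: they do not depend on the trainable weights.
#'
#' @param m Nonnegative `T x input_dim` input matrix (one session).
#' @param head A `model_head` with kind `"stpanet"`.
#' @param params Optional [synapse_params()] override (defaults to the
#'   head's).
#' @param initial Optional initial [synapse_state()]; defaults to rested.
#' @return A `model_forward` object: `prob` (length T), `hidden` (T x 16),
#'   `effective` (T x 64) and the full `trajectory`.
#' @export
stpanet_forward <- function(m, head, params = NULL, initial = NULL) {
  stopifnot(inherits(head, "model_head"))
  plasticity_forward(m, head, params %||% head$config$synapse, initial)
}

#' Forward pass of the depression-only plasticity head
#'
#' Identical to [stpanet_forward()] but with the release probability
#' pinned at `u0` (no gliotransmitter dynamics): the astrocytic increment
#' is zeroed, which reduces the integrator to pure Tsodyks--Markram
#' depression.
#'
#' @inheritParams stpanet_forward
#' @export
stpnet_forward <- function(m, head, params = NULL, initial = NULL) {
  stopifnot(inherits(head, "model_head"))
  p <- depression_only_params(params %||% head$config$synapse)
  plasticity_forward(m, head, p, initial)
}

#' Forward pass of the recurrent baseline head
#'
#' `hidden_t = tanh(W_in m_t + W_rec hidden_{t-1} + b)`, logistic readout
#' per step; no synaptic state.
#'
#' @param m Real-valued `T x input_dim` input matrix.
#' @param head A `model_head` with kind `"rnn"`.
#' @param h0 Optional initial hidden state (defaults to zeros).
#' @return A `model_forward` object with `prob` and `hidden`.
#' @export
rnn_forward <- function(m, head, h0 = NULL) {
  stopifnot(inherits(head, "model_head"), head$config$model_kind == "rnn")
  w <- head$weights
  t_steps <- nrow(m)
  nh <- head$config$hidden_dim
  h <- if (is.null(h0)) numeric(nh) else rep_len(h0, nh)
  hs <- matrix(NA_real_, t_steps, nh)
  for (t in seq_len(t_steps)) {
    h <- tanh(as.vector(m[t, ] %*% w$w1) + as.vector(h %*% w$w_rec) + w$b1)
    hs[t, ] <- h
  }
  prob <- as.vector(logistic(hs %*% w$w2 + w$b2))
  structure(list(prob = prob, hidden = hs, model_kind = "rnn"),
            class = "model_forward")
}

#' Dispatch a forward pass by model kind
#'
#' @param head A `model_head`.
#' @param m Input matrix for one session.
#' @return A `model_forward` object.
#' @export
forward_model <- function(head, m) {
  switch(head$config$model_kind,
         stpanet = stpanet_forward(m, head),
         stpnet = stpnet_forward(m, head),
         rnn = rnn_forward(m, head))
}

#' Per-trial response probability at the decision step
#'
#' Extracts the model output at the session's event flash, optionally
#' max-pooled over a short post-event window.
#'
#' @param prob Per-step probability vector from a forward pass.
#' @param session A [generate_session()] result, or an integer step.
#' @param window Number of steps in the readout window (>= 1). Default 1.
#' @return The per-trial response probability.
#' @export
readout <- function(prob, session, window = 1L) {
  step <- if (inherits(session, "session")) session$event_step else
    as.integer(session)
  window <- as.integer(window)
  if (window < 1L) stop_param("window must be >= 1")
  if (step < 1L || step > length(prob)) {
    stop_param("readout step ", step, " outside 1..", length(prob))
  }
  max(prob[step:min(step + window - 1L, length(prob))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
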