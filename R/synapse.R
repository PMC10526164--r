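#' Parameters of the depressing-synapse/astrocyte model
#'
#' Bundles the constants of the mean-field tripartite synapse: a
#' Tsodyks--Markram style depressing synapse whose release probability is
#' modulated by an astrocytic gliotransmitter variable. Time constants are
#' expressed in conventional units, where one unit is one simulation step
#' (the 250 ms display time of one image flash).
#'
#' The dynamics for one input unit with presynaptic drive \eqn{a(t) \ge 0}
#' are
#' \deqn{dx/dt = (1 - x)/\tau_D - u\,x\,a(t)}
#' \deqn{dy/dt = -y/\tau_y + \beta H_y(x)}
#' \deqn{u(y) = u_0 + \Delta u_0 / (1 + e^{-50 (y - y_{thr})})}
#' with the resource-activation sigmoid
#' \eqn{H_y(x) = 1/(1 + e^{-20 (x - x_{thr})})}. \eqn{x} is the available
#' synaptic resource fraction, \eqn{y} the gliotransmitter level and
#' \eqn{u} the instantaneous release probability.
#'
#' @param tau_d Depression recovery time constant (> 0). Default 6.
#' @param u0 Baseline release probability, in (0, 1). Default 0.23.
#' @param delta_u0 Astrocytic increment to the release probability;
#'   `u0 + delta_u0` must not exceed 1. Default 0.305.
#' @param tau_y Gliotransmitter relaxation time constant (> 0). Default 1.8.
#' @param beta Gliotransmitter production gain (>= 0). Default 0.4375.
#' @param x_thr Threshold on `x` for gliotransmitter production. Default 0.5.
#' @param y_thr Threshold on `y` for release-probability modulation.
#'   Default 0.573.
#' @param slope_x Slope of the resource sigmoid \eqn{H_y}. Default 20.
#' @param slope_y Slope of the release-probability sigmoid. Default 50.
#' @return An object of class `synapse_params`.
#' @examples
#' p <- synapse_params()
#' release_probability(0, p)   # ~ u0: no gliotransmitter present
#' @export
synapse_params <- function(tau_d = 6, u0 = 0.23, delta_u0 = 0.305,
                           tau_y = 1.8, beta = 0.4375,
                           x_thr = 0.5, y_thr = 0.573,
                           slope_x = 20, slope_y = 50) {
  check_scalar(tau_d, "tau_d", lower = 0, strict_lower = TRUE)
  check_scalar(tau_y, "tau_y", lower = 0, strict_lower = TRUE)
  check_scalar(beta, "beta", lower = 0)
  check_scalar(u0, "u0", lower = 0, strict_lower = TRUE, upper = 1)
  check_scalar(delta_u0, "delta_u0", lower = 0)
  if (u0 + delta_u0 > 1) stop_param("u0 + delta_u0 must not exceed 1")
  check_scalar(x_thr, "x_thr")
  check_scalar(y_thr, "y_thr")
  check_scalar(slope_x, "slope_x", lower = 0, strict_lower = TRUE)
  check_scalar(slope_y, "slope_y", lower = 0, strict_lower = TRUE)
  structure(
    list(tau_d = tau_d, u0 = u0, delta_u0 = delta_u0, tau_y = tau_y,
         beta = beta, x_thr = x_thr, y_thr = y_thr,
         slope_x = slope_x, slope_y = slope_y),
    class = "synapse_params"
  )
}

#' @export
print.synapse_params <- function(x, ...) {
  cat("Tripartite synapse parameters (conventional time units)\n")
  cat(sprintf("  depression : tau_d = %g, u0 = %g\n", x$tau_d, x$u0))
  cat(sprintf("  astrocyte  : delta_u0 = %g, tau_y = %g, beta = %g\n",
              x$delta_u0, x$tau_y, x$beta))
  cat(sprintf("  thresholds : x_thr = %g (slope %g), y_thr = %g (slope %g)\n",
              x$x_thr, x$slope_x, x$y_thr, x$slope_y))
  invisible(x)
}

#' Per-unit dynamical state of the synapse model
#'
#' Holds the vectors `x` (available resource fraction in \[0, 1\]), `y`
#' (gliotransmitter level, >= 0) and `u` (release probability, the image of
#' `y` under [release_probability()]), one entry per input unit. The
#' default is the rested state x = 1, y = 0, u = u(0).
#'
#' @param n_units Number of input units.
#' @param params A [synapse_params()] object (sets the rested `u`).
#' @param x,y Optional initial values, recycled to `n_units`.
#' @return An object of class `synapse_state`.
#' @export
synapse_state <- function(n_units = 1L, params = synapse_params(),
                          x = 1, y = 0) {
  n_units <- as.integer(n_units)
  if (n_units < 1L) stop_param("n_units must be >= 1")
  x <- rep_len(as.numeric(x), n_units)
  y <- rep_len(as.numeric(y), n_units)
  if (any(x < 0 | x > 1)) stop_param("x must lie in [0, 1]")
  if (any(y < 0)) stop_param("y must be >= 0")
  structure(list(x = x, y = y, u = release_probability(y, params)),
            class = "synapse_state")
}

#' Resource-activation sigmoid of the astrocyte pathway
#'
#' The logistic gate \eqn{H_y(x) = 1 / (1 + e^{-s_x (x - x_{thr})})} that
#' converts the available-resource level into a gliotransmitter production
#' rate. Strictly increasing, equal to 1/2 at `x_thr`.
#'
#' @param x Resource level(s); any real values.
#' @param params A [synapse_params()] object.
#' @return Values in (0, 1), same length as `x`.
#' @export
hy_activation <- function(x, params = synapse_params()) {
  1 / (1 + exp(-params$slope_x * (x - params$x_thr)))
}

#' Release probability as a function of gliotransmitter level
#'
#' The sigmoid map \eqn{u(y) = u_0 + \Delta u_0 /
#' (1 + e^{-s_y (y - y_{thr})})}. Nondecreasing in `y` and confined to
#' `(u0, u0 + delta_u0)`; at `y = y_thr` it equals `u0 + delta_u0 / 2`.
#'
#' @param y Gliotransmitter level(s).
#' @param params A [synapse_params()] object.
#' @return Release probabilities, same length as `y`.
#' @export
release_probability <- function(y, params = synapse_params()) {
  params$u0 + params$delta_u0 / (1 + exp(-params$slope_y * (y - params$y_thr)))
}

#' One explicit-Euler step of the synapse/astrocyte dynamics
#'
#' Advances each unit by `dt`: the resource is updated from the current
#' `(x, u)` and drive, the gliotransmitter from the current `x`, and the
#' release probability is then recomputed from the new `y`. The resource is
#' clamped to \[0, 1\] after the step, since a large drive at `dt = 1` can
#' overshoot the origin; clamping preserves the fraction semantics.
#'
#' @param state A [synapse_state()].
#' @param drive Nonnegative presynaptic activity per unit (recycled).
#' @param params A [synapse_params()].
#' @param dt Positive step size in conventional units. Default 1
#'   (one 250 ms flash).
#' @return The advanced `synapse_state`.
#' @export
euler_step <- function(state, drive, params = synapse_params(), dt = 1) {
  if (!inherits(state, "synapse_state")) stop_param("state must be a synapse_state")
  if (!is.numeric(drive) || any(!is.finite(drive)) || any(drive < 0)) {
    stop_param("drive must be finite and >= 0")
  }
  check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  drive <- rep_len(as.numeric(drive), length(state$x))
  x_new <- state$x + dt * ((1 - state$x) / params$tau_d -
                             state$u * state$x * drive)
  x_new <- pmin(pmax(x_new, 0), 1)
  y_new <- state$y + dt * (-state$y / params$tau_y +
                             params$beta * hy_activation(state$x, params))
  y_new <- pmax(y_new, 0)
  structure(list(x = x_new, y = y_new,
                 u = release_probability(y_new, params)),
            class = "synapse_state")
}

#' Integrate the synapse dynamics along a drive trace
#'
#' Iterates [euler_step()] over a presynaptic activity trace and records
#' the state *entering* each step, so the state at step t depends only on
#' drives at steps < t. The effective (transmitted) activity at step t is
#' `u[t] * x[t] * drive[t]`.
#'
#' @param drive Numeric vector (one unit) or a T x n matrix of nonnegative
#'   drives, one row per time step.
#' @param params A [synapse_params()].
#' @param initial A [synapse_state()] with as many units as `drive` has
#'   columns; defaults to the rested state.
#' @param dt Step size in conventional units (default 1).
#' @return An object of class `synapse_trajectory`: a list with `times`
#'   (step indices), matrices `x_series`, `y_series`, `u_series`,
#'   `effective_series` (T x n), the `drive` matrix, `dt` and `params`.
#' @examples
#' traj <- simulate_trace(rep(c(1, 0, 0), 10))  # flash/gray/gray drive
#' head(traj$x_series)
#' @export
simulate_trace <- function(drive, params = synapse_params(),
                           initial = NULL, dt = 1) {
  if (is.null(dim(drive))) drive <- matrix(as.numeric(drive), ncol = 1L)
  drive <- as.matrix(drive)
  if (nrow(drive) < 1L) stop_param("drive must be nonempty")
  if (any(!is.finite(drive)) || any(drive < 0)) {
    stop_param("drive must be finite and >= 0")
  }
  n_steps <- nrow(drive)
  n_units <- ncol(drive)
  if (is.null(initial)) initial <- synapse_state(n_units, params)
  if (length(initial$x) != n_units) {
    stop_param("initial state has ", length(initial$x),
               " units but drive has ", n_units, " columns")
  }
  xs <- ys <- us <- matrix(NA_real_, n_steps, n_units)
  st <- initial
  for (t in seq_len(n_steps)) {
    xs[t, ] <- st$x
    ys[t, ] <- st$y
    us[t, ] <- st$u
    st <- euler_step(st, drive[t, ], params, dt)
  }
  structure(
    list(times = seq_len(n_steps), x_series = xs, y_series = ys,
         u_series = us, effective_series = us * xs * drive,
         drive = drive, dt = dt, params = params, final_state = st),
    class = "synapse_trajectory"
  )
}

#' @export
print.synapse_trajectory <- function(x, ...) {
  cat(sprintf("Synapse trajectory: %d steps x %d units (dt = %g)\n",
              nrow(x$x_series), ncol(x$x_series), x$dt))
  cat(sprintf("  final x range [%.3f, %.3f], u range [%.3f, %.3f]\n",
              min(x$x_series[nrow(x$x_series), ]),
              max(x$x_series[nrow(x$x_series), ]),
              min(x$u_series), max(x$u_series)))
  invisible(x)
}

#' Export a trajectory as a long-format data frame
#'
#' One row per (step, unit) with columns step, unit, x, y, u, drive and
#' effective, suitable for CSV export and plotting.
#'
#' @param traj A `synapse_trajectory`.
#' @param file Optional path; when given the table is also written as CSV.
#' @return The data frame, invisibly when `file` is given.
#' @export
trajectory_to_df <- function(traj, file = NULL) {
  stopifnot(inherits(traj, "synapse_trajectory"))
  n <- ncol(traj$x_series)
  t <- nrow(traj$x_series)
  df <- data.frame(
    step = rep(seq_len(t), times = n),
    unit = rep(seq_len(n), each = t),
    x = as.vector(traj$x_series),
    y = as.vector(traj$y_series),
    u = as.vector(traj$u_series),
    drive = as.vector(traj$drive),
    effective = as.vector(traj$effective_series)
  )
  if (!is.null(file)) {
    utils::write.csv(df, file, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Equilibrium of the synapse dynamics under constant drive
#'
#' Solves the self-consistent fixed point
#' \eqn{(1 - x^*)/\tau_D = u^* x^* a}, \eqn{y^* = \tau_y \beta H_y(x^*)},
#' \eqn{u^* = u(y^*)}. Eliminating y and u leaves the scalar equation
#' \eqn{x = F(x)} with \eqn{F(x) = 1 / (1 + \tau_D\, u(y(x))\, a)}
#' nonincreasing in x, so \eqn{x - F(x)} is strictly increasing and the
#' equilibrium is unique; it is bracketed on \[0, 1\] and found by
#' bisection (plain damped fixed-point iteration oscillates between the
#' branches of the steep release-probability sigmoid for intermediate
#' drives). With `u_fixed` supplied, `u` is pinned to that constant (used
#' to validate against the closed-form depression-only equilibrium
#' \eqn{x^* = (1/\tau_D) / (1/\tau_D + u a)}).
#'
#' @param drive_const Constant nonnegative drive.
#' @param params A [synapse_params()].
#' @param u_fixed Optional fixed release probability overriding the
#'   astrocyte map.
#' @param tol Convergence tolerance on x (default 1e-12).
#' @param max_iter Iteration cap; exceeding it is a numerical error.
#' @return A [synapse_state()] at equilibrium (one unit).
#' @export
steady_state <- function(drive_const, params = synapse_params(),
                         u_fixed = NULL, tol = 1e-12, max_iter = 200L) {
  check_scalar(drive_const, "drive_const", lower = 0)
  u_of_x <- function(x) {
    if (!is.null(u_fixed)) return(u_fixed)
    release_probability(params$tau_y * params$beta *
                          hy_activation(x, params), params)
  }
  f_map <- function(x) 1 / (1 + params$tau_d * u_of_x(x) * drive_const)
  lo <- 0; hi <- 1
  iter <- 0L
  while (hi - lo > tol) {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop("steady_state did not converge within ", max_iter, " iterations")
    }
    mid <- (lo + hi) / 2
    if (mid - f_map(mid) < 0) lo <- mid else hi <- mid
  }
  x <- (lo + hi) / 2
  y <- params$tau_y * params$beta * hy_activation(x, params)
  structure(list(x = x, y = y, u = u_of_x(x)), class = "synapse_state")
}
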