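#' Logistic squash of raw model outputs
#'
#' Maps raw outputs elementwise through \eqn{S(\omega) = 1/(1+e^{-\omega})}
#' so response values lie strictly in (0, 1).
#'
#' @param omega Finite numeric vector.
#' @return Probabilities in (0, 1).
#' @export
squash <- function(omega) {
  if (any(!is.finite(omega))) stop_param("omega must be finite")
  logistic(omega)
}

#' Sample binary responses from response probabilities
#'
#' Independent Bernoulli draws, element i with parameter `probs[i]`.
#'
#' @param probs Probabilities in \[0, 1\].
#' @param seed Optional integer seed.
#' @return 0/1 integer vector.
#' @export
sample_responses <- function(probs, seed = NULL) {
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1)) {
    stop_param("probabilities must lie in [0, 1]")
  }
  with_seed(seed, stats::rbinom(length(probs), 1L, probs))
}

#' Round-robin block assignment within each trial class
#'
#' Distributes Go and Catch trials over `n_blocks` so that every block
#' contains both classes (required for per-block hit/false-alarm rates).
#'
#' @param labels +1/-1 trial labels.
#' @param n_blocks Number of blocks (>= 2).
#' @return Integer block id per trial.
#' @export
block_assignment <- function(labels, n_blocks) {
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 2L) stop_param("n_blocks must be >= 2")
  ids <- integer(length(labels))
  for (cls in c(1L, -1L)) {
    sel <- which(labels == cls)
    if (length(sel) < n_blocks) {
      stop_param("class ", cls, " has fewer trials (", length(sel),
                 ") than blocks (", n_blocks, ")")
    }
    ids[sel] <- rep_len(seq_len(n_blocks), length(sel))
  }
  ids
}

#' Per-trial detection outcome container
#'
#' Bundles per-trial response probabilities, sampled (or analytic) binary
#' responses, +1/-1 Go/Catch labels, block ids for variance estimation and
#' the (previous image, current image) transition of each trial. When
#' `predictions` is omitted a Bernoulli draw is taken from the current RNG
#' stream.
#'
#' @param probs Per-trial response probabilities in (0, 1\].
#' @param labels +1 (Go) / -1 (Catch) per trial.
#' @param predictions Optional 0/1 responses (or expected responses in
#'   \[0, 1\] for the analytic mode).
#' @param block_ids Integer block id per trial (see [block_assignment()]).
#' @param pre_images,post_images Optional image identities before/at the
#'   event, for response-matrix bookkeeping.
#' @param omega Optional raw outputs before the squash.
#' @return An object of class `detection_outcome`.
#' @export
detection_outcome <- function(probs, labels, predictions = NULL,
                              block_ids = NULL, pre_images = NULL,
                              post_images = NULL, omega = NULL) {
  n <- length(probs)
  if (length(labels) != n) stop_param("labels and probs lengths differ")
  if (!all(labels %in% c(1L, -1L))) stop_param("labels must be +1 or -1")
  if (any(probs < 0 | probs > 1)) stop_param("probs must lie in [0, 1]")
  if (is.null(predictions)) predictions <- sample_responses(probs)
  if (length(predictions) != n) stop_param("one prediction per trial needed")
  if (any(predictions < 0 | predictions > 1)) {
    stop_param("predictions must lie in [0, 1]")
  }
  if (!is.null(block_ids) && length(block_ids) != n) {
    stop_param("one block id per trial needed")
  }
  structure(
    list(omega = omega, probs = probs, predictions = predictions,
         labels = as.integer(labels), block_ids = block_ids,
         pre_images = pre_images, post_images = post_images),
    class = "detection_outcome"
  )
}

#' Hit and false-alarm rates of a detection outcome
#'
#' The hit rate is the mean response over Go trials (label +1); the
#' false-alarm rate is the mean response over Catch trials (label -1).
#'
#' @param outcome A [detection_outcome()], requiring at least one trial of
#'   each class.
#' @return Named list with `hit_rate` and `false_rate`.
#' @export
hit_false_rates <- function(outcome) {
  stopifnot(inherits(outcome, "detection_outcome"))
  go <- outcome$labels == 1L
  if (!any(go) || !any(!go)) {
    stop_param("need at least one Go and one Catch trial")
  }
  list(hit_rate = sum(outcome$predictions[go]) / sum(go),
       false_rate = sum(outcome$predictions[!go]) / sum(!go))
}

#' Detectability index (d-prime) of a detection outcome
#'
#' Rates are computed per block; the index is the difference between the
#' mean block hit rate and the mean block false-alarm rate, divided by the
#' standard deviation of the per-block (hit - false) differences. The
#' divisor is floored at `sigma_floor` so perfect detectors stay finite.
#' This ratio form is the task's native index; the classical
#' Gaussian-inverse variant is available separately as
#' [dprime_classical()].
#'
#' @param outcome A [detection_outcome()] with block ids covering at least
#'   two blocks, unless `fixed_sigma` is supplied.
#' @param sigma_floor Lower bound on the variability term. Default 1e-6.
#' @param fixed_sigma Optional externally supplied sigma (bypasses the
#'   block requirement).
#' @return An object of class `dprime_result` with `hit_rate`,
#'   `false_rate` (means over blocks), `sigma`, `dprime`, `n_go`,
#'   `n_catch` and the per-block rate table.
#' @export
dprime <- function(outcome, sigma_floor = 1e-6, fixed_sigma = NULL) {
  stopifnot(inherits(outcome, "detection_outcome"))
  if (is.null(outcome$block_ids)) {
    if (is.null(fixed_sigma)) {
      stop_param("block ids are required unless fixed_sigma is supplied")
    }
    r <- hit_false_rates(outcome)
    blocks <- data.frame(block = 1L, hit = r$hit_rate, false = r$false_rate)
  } else {
    ids <- sort(unique(outcome$block_ids))
    if (length(ids) < 2L && is.null(fixed_sigma)) {
      stop_param("at least two blocks are needed to estimate sigma")
    }
    blocks <- do.call(rbind, lapply(ids, function(b) {
      sel <- outcome$block_ids == b
      sub <- detection_outcome(outcome$probs[sel], outcome$labels[sel],
                               outcome$predictions[sel])
      r <- hit_false_rates(sub)
      data.frame(block = b, hit = r$hit_rate, false = r$false_rate)
    }))
  }
  diffs <- blocks$hit - blocks$false
  sigma <- if (!is.null(fixed_sigma)) fixed_sigma else stats::sd(diffs)
  sigma <- max(sigma, sigma_floor)
  structure(
    list(hit_rate = mean(blocks$hit), false_rate = mean(blocks$false),
         sigma = sigma, dprime = (mean(blocks$hit) - mean(blocks$false)) /
           sigma,
         n_go = sum(outcome$labels == 1L),
         n_catch = sum(outcome$labels == -1L), blocks = blocks),
    class = "dprime_result"
  )
}

#' @export
print.dprime_result <- function(x, ...) {
  cat(sprintf("d' = %.3f  (hit %.3f, false alarm %.3f, sigma %.4f; %d Go / %d Catch)\n",
              x$dprime, x$hit_rate, x$false_rate, x$sigma, x$n_go, x$n_catch))
  invisible(x)
}

#' Classical Gaussian-inverse d-prime (labelled alternative)
#'
#' `qnorm(hit) - qnorm(false)` with rates clipped away from 0 and 1. Not
#' the task's native index; provided for comparison only.
#'
#' @param outcome A [detection_outcome()].
#' @param clip Rate clipping bound. Default 0.01.
#' @return A single number.
#' @export
dprime_classical <- function(outcome, clip = 0.01) {
  r <- hit_false_rates(outcome)
  h <- min(max(r$hit_rate, clip), 1 - clip)
  f <- min(max(r$false_rate, clip), 1 - clip)
  stats::qnorm(h) - stats::qnorm(f)
}

#' Stimulus-transition response matrix
#'
#' Cell (i, j) holds the mean response over trials in which image i was
#' followed by image j at the event flash; with 8 images there are 64
#' possible transitions. Diagonal cells can only come from Catch
#' (sham-change) trials. Cells with no trials are `NA` and reported, not
#' invented.
#'
#' @param outcome A [detection_outcome()] carrying `pre_images` and
#'   `post_images`.
#' @param n_images Matrix dimension (default: largest image id seen).
#' @return An object of class `response_matrix` with `probs`
#'   (n x n matrix) and `counts`.
#' @export
response_matrix <- function(outcome, n_images = NULL) {
  stopifnot(inherits(outcome, "detection_outcome"))
  if (is.null(outcome$pre_images) || is.null(outcome$post_images)) {
    stop_param("outcome lacks transition bookkeeping (pre/post images)")
  }
  n_images <- as.integer(n_images %||%
                           max(outcome$pre_images, outcome$post_images))
  probs <- matrix(NA_real_, n_images, n_images)
  counts <- matrix(0L, n_images, n_images)
  for (i in seq_len(n_images)) {
    for (j in seq_len(n_images)) {
      sel <- outcome$pre_images == i & outcome$post_images == j
      counts[i, j] <- sum(sel)
      if (any(sel)) probs[i, j] <- mean(outcome$predictions[sel])
    }
  }
  structure(list(probs = probs, counts = counts), class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  n <- nrow(x$probs)
  cat(sprintf("Response matrix: %d x %d (%d empty cells)\n", n, n,
              sum(is.na(x$probs))))
  cat(sprintf("  mean off-diagonal %.3f, mean diagonal %.3f\n",
              mean(x$probs[row(x$probs) != col(x$probs)], na.rm = TRUE),
              mean(diag(x$probs), na.rm = TRUE)))
  invisible(x)
}

#' Symmetric / antisymmetric decomposition of a square matrix
#'
#' `Msym = (M + t(M)) / 2`, `Mantisym = (M - t(M)) / 2`; the two parts sum
#' back to `M` exactly.
#'
#' @param m A square numeric matrix.
#' @return List with `m_sym` and `m_antisym`.
#' @export
sym_antisym <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop_param("matrix must be square")
  list(m_sym = (m + t(m)) / 2, m_antisym = (m - t(m)) / 2)
}

#' Asymmetry index of a (response) matrix
#'
#' The naive ratio of identical norms is always 1 and carries no
#' information, so the index implemented here follows the
#' difference-over-sum reading: after centring the matrix by its grand
#' mean (default convention), \eqn{q = (\|A\|_F - \|S\|_F) /
#' (\|S\|_F + \|A\|_F)} where S and A are the symmetric and antisymmetric
#' parts. q lies in \[-1, 1\]: -1 for an exactly symmetric (centred)
#' matrix, +1 for a purely antisymmetric one. The convention used is
#' recorded in the result; `"norm-diff"` skips the centring and
#' `"classic"` returns \eqn{\|A\|_F / \|S\|_F}.
#'
#' @param m Square numeric matrix (`NA` cells are treated as 0 after a
#'   warning-free internal replacement; pass complete matrices when
#'   possible).
#' @param convention `"centered-norm-diff"` (default), `"norm-diff"` or
#'   `"classic"`.
#' @return An object of class `asymmetry_result` with `m_sym`,
#'   `m_antisym`, `q` (NA with `degenerate = TRUE` for a zero matrix) and
#'   `convention`.
#' @export
asymmetry_index <- function(m, convention = c("centered-norm-diff",
                                              "norm-diff", "classic")) {
  convention <- match.arg(convention)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop_param("matrix must be square")
  m[is.na(m)] <- 0
  centred <- if (convention == "centered-norm-diff") m - mean(m) else m
  parts <- sym_antisym(centred)
  ns <- sqrt(sum(parts$m_sym^2))
  na <- sqrt(sum(parts$m_antisym^2))
  degenerate <- (ns + na) == 0
  q <- if (degenerate) {
    NA_real_
  } else if (convention == "classic") {
    na / max(ns, .Machine$double.eps)
  } else {
    (na - ns) / (ns + na)
  }
  structure(
    list(m_sym = parts$m_sym, m_antisym = parts$m_antisym, q = q,
         degenerate = degenerate, convention = convention),
    class = "asymmetry_result"
  )
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat(sprintf("Asymmetry index q = %s (%s%s)\n",
              if (is.na(x$q)) "NA (degenerate)" else sprintf("%.4f", x$q),
              x$convention,
              if (x$degenerate) ", zero matrix" else ""))
  invisible(x)
}
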