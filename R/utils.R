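#' Evaluate an expression under a temporary RNG state
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so seeded helpers do not perturb the caller's
#' random stream. With `seed = NULL` the expression simply uses the
#' current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a child seed from a base seed
#'
#' Deterministic splitting of one user-facing seed into independent
#' sub-seeds (per run, per model, per epoch). Kept below 2^31 - 1.
#'
#' @param seed Base integer seed.
#' @param ... Integer offsets identifying the consumer.
#' @return An integer seed.
#' @keywords internal
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  acc <- 0
  for (p in parts) {
    acc <- (acc * 69069 + as.double(p) + 1) %% 2147483647
  }
  as.integer(acc)
}

stop_param <- function(...) {
  stop(structure(
    class = c("astromem_param_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_param(name, " must be a finite numeric scalar")
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stop_param(name, " = ", format(x), " is outside the allowed range")
  }
  invisible(x)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

logistic <- function(x) 1 / (1 + exp(-x))
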