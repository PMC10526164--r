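#' Configuration of the visual change-detection task
#'
#' Describes one simulated session: a train of image flashes (250 ms each
#' by default) separated by gray-screen steps (500 ms, i.e. two steps), with
#' one change (Go) or sham-change (Catch) event per session and a small
#' fraction of randomly omitted flashes. Omissions never fall on the flash
#' immediately preceding the event, mirroring the behavioural protocol in
#' which omissions never precede a real or fictitious change.
#'
#' @param length_ms Session duration in ms; must be divisible by
#'   `time_step_ms`. Default 50000.
#' @param time_step_ms Duration of one flash / one simulation step in ms.
#'   Default 250.
#' @param gray_steps Number of gray steps between flashes. Default 2.
#' @param n_images Number of distinct stimulus images (>= 2). Default 8.
#' @param omission_rate Probability that a flash is omitted, in \[0, 1).
#'   Default 0.05.
#' @param min_repeats,max_repeats Bounds on how many flashes of the initial
#'   image precede the change/sham-change event. Defaults 4 and 11.
#' @return An object of class `task_config`.
#' @export
task_config <- function(length_ms = 50000, time_step_ms = 250,
                        gray_steps = 2L, n_images = 8L,
                        omission_rate = 0.05,
                        min_repeats = 4L, max_repeats = 11L) {
  check_scalar(length_ms, "length_ms", lower = 0, strict_lower = TRUE)
  check_scalar(time_step_ms, "time_step_ms", lower = 0, strict_lower = TRUE)
  if (length_ms %% time_step_ms != 0) {
    stop_param("length_ms (", length_ms, ") is not divisible by time_step_ms (",
               time_step_ms, ")")
  }
  check_scalar(omission_rate, "omission_rate", lower = 0, upper = 1,
               strict_upper = TRUE)
  n_images <- as.integer(n_images)
  if (n_images < 2L) stop_param("n_images must be >= 2")
  gray_steps <- as.integer(gray_steps)
  if (gray_steps < 0L) stop_param("gray_steps must be >= 0")
  min_repeats <- as.integer(min_repeats)
  max_repeats <- as.integer(max_repeats)
  if (min_repeats < 1L || min_repeats > max_repeats) {
    stop_param("need 1 <= min_repeats <= max_repeats")
  }
  structure(
    list(length_ms = length_ms, time_step_ms = time_step_ms,
         gray_steps = gray_steps, n_images = n_images,
         omission_rate = omission_rate,
         min_repeats = min_repeats, max_repeats = max_repeats),
    class = "task_config"
  )
}

#' Number of simulation steps in a session
#'
#' One step equals one flash duration, so a 50,000 ms session sampled at
#' 250 ms spans 200 conventional units.
#'
#' @param config A [task_config()].
#' @return Integer step count.
#' @export
n_steps <- function(config) {
  stopifnot(inherits(config, "task_config"))
  as.integer(config$length_ms / config$time_step_ms)
}

#' Generate one change-detection session
#'
#' Builds the flash schedule (flashes every `1 + gray_steps` steps starting
#' at step 1), places one event after a uniformly drawn number of repeats in
#' `[min_repeats, max_repeats]`, switches to a different uniformly drawn
#' image on Go trials (sham-change keeps the image on Catch trials), and
#' draws independent omissions at `omission_rate` for every flash except
#' the one immediately preceding the event and the event flash itself (the
#' readout flash must be visible for the trial to be scorable).
#'
#' @param config A [task_config()].
#' @param label +1 for a Go trial, -1 for a Catch trial.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `session` with fields `n_steps`,
#'   `flash_steps`, `image_ids`, `omitted`, `event_flash` (index into the
#'   flash train), `event_step` (step index of the event flash), `label`,
#'   `pre_image`, `post_image` and the generating `config`.
#' @export
generate_session <- function(config, label, seed = NULL) {
  stopifnot(inherits(config, "task_config"))
  if (!label %in% c(1, -1)) stop_param("label must be +1 (Go) or -1 (Catch)")
  with_seed(seed, {
    total <- n_steps(config)
    period <- 1L + config$gray_steps
    flash_steps <- seq.int(1L, total, by = period)
    n_flash <- length(flash_steps)
    if (n_flash < config$max_repeats + 2L) {
      stop_param("session too short: ", n_flash, " flashes cannot host ",
                 config$max_repeats, " pre-event repeats plus the event")
    }
    repeats <- sample.int(config$max_repeats - config$min_repeats + 1L, 1L) +
      config$min_repeats - 1L
    event_flash <- repeats + 1L
    pre_image <- sample.int(config$n_images, 1L)
    post_image <- if (label == 1) {
      others <- setdiff(seq_len(config$n_images), pre_image)
      others[sample.int(length(others), 1L)]
    } else {
      pre_image
    }
    image_ids <- c(rep(pre_image, repeats),
                   rep(post_image, n_flash - repeats))
    omitted <- stats::runif(n_flash) < config$omission_rate
    omitted[c(event_flash - 1L, event_flash)] <- FALSE
    structure(
      list(n_steps = total, flash_steps = flash_steps,
           image_ids = image_ids, omitted = omitted,
           event_flash = event_flash,
           event_step = flash_steps[event_flash],
           label = as.integer(label),
           pre_image = pre_image, post_image = post_image,
           config = config),
      class = "session"
    )
  })
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("%s session: %d steps, %d flashes, event at step %d (%d -> %d)\n",
              if (x$label == 1) "Go" else "Catch",
              x$n_steps, length(x$flash_steps), x$event_step,
              x$pre_image, x$post_image))
  invisible(x)
}

#' Encode a session as a model input matrix
#'
#' Row t of the result is the feature vector of the image flashed at step t
#' when a non-omitted flash occurs there, and the zero vector during gray
#' screens and omitted flashes.
#'
#' @param session A [generate_session()] result.
#' @param bank A [feature_bank()] with at least `n_images` rows.
#' @return A `n_steps x dim` nonnegative matrix.
#' @export
encode_session <- function(session, bank) {
  stopifnot(inherits(session, "session"), inherits(bank, "feature_bank"))
  if (max(session$image_ids) > nrow(bank$vectors)) {
    stop_param("session references image ", max(session$image_ids),
               " but the bank has only ", nrow(bank$vectors), " rows")
  }
  m <- matrix(0, session$n_steps, ncol(bank$vectors))
  shown <- !session$omitted
  m[session$flash_steps[shown], ] <- bank$vectors[session$image_ids[shown], ,
                                                  drop = FALSE]
  m
}

#' Serialize a session to JSON (and back)
#'
#' @param session A `session` object.
#' @param file Optional path to write to.
#' @return JSON string (invisible when written to `file`).
#' @export
session_to_json <- function(session, file = NULL) {
  stopifnot(inherits(session, "session"))
  payload <- session[c("n_steps", "flash_steps", "image_ids", "omitted",
                       "event_flash", "event_step", "label",
                       "pre_image", "post_image")]
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}

#' @rdname session_to_json
#' @param json JSON string or path produced by [session_to_json()].
#' @param config The [task_config()] the session was generated under.
#' @export
session_from_json <- function(json, config) {
  payload <- jsonlite::fromJSON(json)
  structure(
    list(n_steps = as.integer(payload$n_steps),
         flash_steps = as.integer(payload$flash_steps),
         image_ids = as.integer(payload$image_ids),
         omitted = as.logical(payload$omitted),
         event_flash = as.integer(payload$event_flash),
         event_step = as.integer(payload$event_step),
         label = as.integer(payload$label),
         pre_image = as.integer(payload$pre_image),
         post_image = as.integer(payload$post_image),
         config = config),
    class = "session"
  )
}

#' Build a batch of encoded Go/Catch trials
#'
#' Generates `n_go` Go and `n_catch` Catch sessions, encodes each against
#' the feature bank and records the per-session decision (readout) step,
#' which is the event step.
#'
#' @param config A [task_config()].
#' @param n_go,n_catch Trial counts (>= 0).
#' @param bank A [feature_bank()].
#' @param seed Optional integer seed.
#' @return An object of class `trial_batch`: list with `sessions`,
#'   `inputs` (list of T x dim matrices), `labels` (+1/-1), and
#'   `readout_steps`.
#' @export
make_batch <- function(config, n_go, n_catch, bank, seed = NULL) {
  stopifnot(n_go >= 0, n_catch >= 0, n_go + n_catch > 0)
  with_seed(seed, {
    labels <- c(rep(1L, n_go), rep(-1L, n_catch))
    sessions <- lapply(labels, function(lb) generate_session(config, lb))
    inputs <- lapply(sessions, encode_session, bank = bank)
    structure(
      list(sessions = sessions, inputs = inputs, labels = labels,
           readout_steps = vapply(sessions, `[[`, integer(1), "event_step"),
           config = config),
      class = "trial_batch"
    )
  })
}

#' @export
print.trial_batch <- function(x, ...) {
  cat(sprintf("Trial batch: %d Go + %d Catch sessions of %d steps\n",
              sum(x$labels == 1), sum(x$labels == -1),
              x$sessions[[1]]$n_steps))
  invisible(x)
}
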