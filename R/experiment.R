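#' Configuration of an end-to-end model-comparison experiment
#'
#' Bundles every nested configuration needed to train and compare the
#' three head kinds on identical evaluation sessions. Within each run the
#' three models are evaluated on the same freshly generated session set
#' (paired comparison), which sharpens between-model contrasts without
#' biasing the means.
#'
#' @param task A [task_config()].
#' @param synapse A [synapse_params()].
#' @param train A [train_config()].
#' @param models Character vector of head kinds to compare.
#' @param n_runs Independent training repetitions per model (default 10).
#' @param n_eval_go,n_eval_catch Evaluation trials per run.
#' @param eval_blocks Blocks for the evaluation d-prime.
#' @param bank A [feature_bank()], or `NULL` to generate a synthetic bank.
#' @param bank_args List of arguments for [synthetic_feature_bank()] when
#'   `bank` is `NULL`.
#' @param out_dir Optional directory for artifacts (CSV tables, JSON
#'   report).
#' @param seed Global integer seed; fully determines the experiment.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(task = task_config(),
                              synapse = synapse_params(),
                              train = train_config(),
                              models = c("stpanet", "stpnet", "rnn"),
                              n_runs = 10L,
                              n_eval_go = 100L, n_eval_catch = 100L,
                              eval_blocks = 10L,
                              bank = NULL,
                              bank_args = list(sparsity = 0.8,
                                               overlap = 0.2),
                              out_dir = NULL, seed = 1L) {
  stopifnot(inherits(task, "task_config"), inherits(train, "train_config"))
  models <- match.arg(models, c("stpanet", "stpnet", "rnn"),
                      several.ok = TRUE)
  if (n_runs < 1L) stop_param("n_runs must be >= 1")
  structure(
    list(task = task, synapse = synapse, train = train, models = models,
         n_runs = as.integer(n_runs), n_eval_go = as.integer(n_eval_go),
         n_eval_catch = as.integer(n_eval_catch),
         eval_blocks = as.integer(eval_blocks), bank = bank,
         bank_args = bank_args, out_dir = out_dir, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Run a full model-comparison experiment
#'
#' For every run and model kind: initialize a head with a derived seed,
#' train it on the change-detection task, evaluate it on the run's shared
#' evaluation sessions, and record d-prime, the stimulus-transition
#' response matrix and the asymmetry index. Aggregates means and standard
#' deviations over runs (standard deviations are `NA` for a single run).
#' Runs that fail are recorded, excluded from aggregates, and reported
#' with a warning.
#'
#' @param config An [experiment_config()].
#' @return An object of class `comparison_report`: per-model summary data
#'   frame, per-run details, the feature bank used and full provenance.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  bank <- config$bank %||% do.call(
    synthetic_feature_bank,
    c(list(n_images = config$task$n_images,
           seed = derive_seed(config$seed, 101L)),
      config$bank_args))
  runs <- list()
  failures <- character(0)
  for (r in seq_len(config$n_runs)) {
    eval_batch <- make_batch(config$task, config$n_eval_go,
                             config$n_eval_catch, bank,
                             seed = derive_seed(config$seed, r, 999L))
    eval_signature <- paste(
      vapply(eval_batch$sessions, function(s) {
        paste(s$label, s$event_step, s$pre_image, s$post_image, sep = ":")
      }, character(1)), collapse = ";")
    for (mi in seq_along(config$models)) {
      kind <- config$models[mi]
      res <- tryCatch({
        hc <- head_config(kind, input_dim = ncol(bank$vectors),
                          synapse = config$synapse)
        head <- init_head(hc, seed = derive_seed(config$seed, r, mi, 1L))
        tc <- config$train
        tc$seed <- derive_seed(config$seed, r, mi, 2L)
        tr <- train_head(head, config$task, bank, tc)
        outcome <- evaluate_head(tr$head, eval_batch,
                                 n_blocks = config$eval_blocks,
                                 seed = derive_seed(config$seed, r, mi, 3L))
        dp <- dprime(outcome)
        rm_ <- response_matrix(outcome, n_images = config$task$n_images)
        asym <- asymmetry_index(rm_$probs)
        list(run = r, model = kind, dprime = dp$dprime,
             hit_rate = dp$hit_rate, false_rate = dp$false_rate,
             asymmetry = asym$q, asym_convention = asym$convention,
             epochs_run = tr$epochs_run, stop_reason = tr$stop_reason,
             response_matrix = rm_, train_result = tr,
             eval_signature = eval_signature)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        msg <- sprintf("run %d model %s failed: %s", r, kind,
                       conditionMessage(res))
        failures <- c(failures, msg)
        warning(msg, call. = FALSE)
      } else {
        runs[[length(runs) + 1L]] <- res
      }
    }
  }
  run_df <- do.call(rbind, lapply(runs, function(x) {
    data.frame(run = x$run, model = x$model, dprime = x$dprime,
               hit_rate = x$hit_rate, false_rate = x$false_rate,
               asymmetry = x$asymmetry, epochs_run = x$epochs_run,
               stop_reason = x$stop_reason)
  }))
  summary_df <- do.call(rbind, lapply(unique(run_df$model), function(k) {
    sub <- run_df[run_df$model == k, ]
    data.frame(
      model = k, n_runs = nrow(sub),
      dprime_mean = mean(sub$dprime),
      dprime_sd = if (nrow(sub) >= 2L) stats::sd(sub$dprime) else NA_real_,
      asymmetry_mean = mean(sub$asymmetry),
      asymmetry_sd = if (nrow(sub) >= 2L) stats::sd(sub$asymmetry) else
        NA_real_)
  }))
  report <- structure(
    list(summary = summary_df, runs = run_df, details = runs, bank = bank,
         failures = failures, config = config),
    class = "comparison_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Model comparison over", max(x$runs$run), "run(s):\n")
  print(x$summary, row.names = FALSE)
  if (length(x$failures)) {
    cat(length(x$failures), "failed run(s) excluded from aggregates\n")
  }
  invisible(x)
}

#' Write experiment artifacts to a directory
#'
#' Emits `summary.csv`, `runs.csv`, per-run response matrices and a JSON
#' report with full provenance (configs and seeds).
#'
#' @param report A [run_experiment()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$runs, file.path(out_dir, "runs.csv"),
                   row.names = FALSE)
  for (d in report$details) {
    utils::write.csv(
      d$response_matrix$probs,
      file.path(out_dir, sprintf("response_matrix_%s_run%d.csv",
                                 d$model, d$run)),
      row.names = FALSE)
  }
  cfg <- report$config
  payload <- list(
    summary = report$summary,
    runs = report$runs,
    failures = report$failures,
    provenance = list(
      seed = cfg$seed, n_runs = cfg$n_runs, models = cfg$models,
      task = unclass(cfg$task), synapse = unclass(cfg$synapse),
      train = unclass(cfg$train),
      bank_provenance = report$bank$provenance,
      package_version = as.character(utils::packageVersion("astromem"))))
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Diagnostic figures for experiment artifacts
#'
#' Renders (as PDF, deterministically for fixed inputs) the four-panel
#' synapse dynamics figure (drive, resource, modulated input,
#' gliotransmitter), the training loss / d-prime curves, and a
#' response-matrix heat map with the diagonal annotated.
#'
#' @param trajectory A `synapse_trajectory`, or `NULL`.
#' @param train_result A `train_result`, or `NULL`.
#' @param resp_matrix A `response_matrix`, or `NULL`.
#' @param out_dir Directory for the figure files.
#' @return Character vector of files written.
#' @export
plot_diagnostics <- function(trajectory = NULL, train_result = NULL,
                             resp_matrix = NULL, out_dir = ".") {
  if (is.null(trajectory) && is.null(train_result) && is.null(resp_matrix)) {
    stop_param("no artifact supplied: need a trajectory, a train_result ",
               "or a resp_matrix")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  if (!is.null(trajectory)) {
    f <- file.path(out_dir, "synapse_dynamics.pdf")
    grDevices::pdf(f, width = 7, height = 8)
    op <- graphics::par(mfrow = c(4, 1), mar = c(3, 4, 2, 1))
    unit1 <- 1L
    graphics::plot(trajectory$drive[, unit1], type = "h", col = "gray30",
                   ylab = "drive", main = "Input activity")
    graphics::plot(trajectory$x_series[, unit1], type = "l", col = "blue",
                   ylim = c(0, 1), ylab = "x", main = "Synaptic efficacy")
    graphics::plot(trajectory$effective_series[, unit1], type = "l",
                   col = "darkgreen", ylab = "u*x*drive",
                   main = "Modulated input")
    graphics::plot(trajectory$y_series[, unit1], type = "l", col = "red",
                   ylab = "y", main = "Gliotransmitter")
    graphics::par(op)
    grDevices::dev.off()
    written <- c(written, f)
  }
  if (!is.null(train_result)) {
    f <- file.path(out_dir, "training_curves.pdf")
    grDevices::pdf(f, width = 7, height = 5)
    op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    graphics::plot(train_result$loss, type = "l", xlab = "epoch",
                   ylab = "loss", main = "Loss")
    graphics::plot(train_result$dprime, type = "l", xlab = "epoch",
                   ylab = "d'", main = "d-prime")
    graphics::abline(h = train_result$train_config$dprime_threshold,
                     lty = 2, col = "gray50")
    graphics::par(op)
    grDevices::dev.off()
    written <- c(written, f)
  }
  if (!is.null(resp_matrix)) {
    f <- file.path(out_dir, "response_matrix.pdf")
    grDevices::pdf(f, width = 6, height = 6)
    pm <- resp_matrix$probs
    n <- nrow(pm)
    graphics::image(seq_len(n), seq_len(n), t(pm[n:1, ]),
                    col = grDevices::hcl.colors(25, "YlOrRd", rev = TRUE),
                    xlab = "current image", ylab = "previous image",
                    main = "Response probability by transition",
                    axes = FALSE, zlim = c(0, 1))
    graphics::axis(1, at = seq_len(n))
    graphics::axis(2, at = seq_len(n), labels = rev(seq_len(n)))
    for (i in seq_len(n)) {
      graphics::text(i, n - i + 1,
                     ifelse(is.na(pm[i, i]), "·",
                            sprintf("%.2f", pm[i, i])), cex = 0.7)
    }
    grDevices::dev.off()
    written <- c(written, f)
  }
  written
}
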