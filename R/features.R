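#' Feature bank of stimulus vectors
#'
#' A bank of `n_images` nonnegative feature vectors (64-dimensional by
#' default) that drive the dynamic-synapse input layer. Banks come either
#' from the FC-64 layer of a trained image encoder or from the synthetic
#' generator [synthetic_feature_bank()]; the two are interchangeable by
#' contract everywhere downstream.
#'
#' @param vectors `n_images x dim` nonnegative matrix; each row must have
#'   at least one nonzero entry.
#' @param provenance `"trained-encoder"` or `"synthetic"`.
#' @param seed Seed recorded for provenance (may be `NA`).
#' @return An object of class `feature_bank`.
#' @export
feature_bank <- function(vectors, provenance = c("synthetic",
                                                 "trained-encoder"),
                         seed = NA_integer_) {
  provenance <- match.arg(provenance)
  vectors <- as.matrix(vectors)
  if (any(!is.finite(vectors)) || any(vectors < 0)) {
    stop_param("feature vectors must be finite and nonnegative")
  }
  if (any(rowSums(vectors) == 0)) {
    stop_param("every feature vector must have at least one nonzero entry")
  }
  structure(list(vectors = vectors, provenance = provenance, seed = seed),
            class = "feature_bank")
}

#' @export
print.feature_bank <- function(x, ...) {
  cat(sprintf("Feature bank: %d images x %d dims (%s), zero fraction %.2f\n",
              nrow(x$vectors), ncol(x$vectors), x$provenance,
              mean(x$vectors == 0)))
  invisible(x)
}

#' Generate a sparse synthetic feature bank
#'
#' Emulates the sparse, nonnegative FC-64 activations of an image encoder
#' without any image data. Each entry of each image vector is drawn from a
#' shared template with probability `overlap` and from an image-specific
#' pattern otherwise; in both sources an entry is zero with probability
#' `sparsity` and otherwise uniform on (0.2, 1.2). The marginal zero
#' fraction therefore equals `sparsity` exactly, `overlap = 1` yields
#' identical rows, and larger `overlap` raises pairwise cosine similarity.
#' Rows that come out all zero are given one nonzero entry so the bank is
#' never degenerate.
#'
#' @param n_images Number of stimulus vectors. Default 8.
#' @param dim Feature dimension. Default 64.
#' @param sparsity Expected zero fraction, in \[0, 1). Default 0.8.
#' @param overlap Probability of sharing the template entry, in \[0, 1\].
#'   Default 0.2.
#' @param seed Optional integer seed.
#' @return A [feature_bank()] with provenance `"synthetic"`.
#' @examples
#' bank <- synthetic_feature_bank(seed = 1)
#' dim(bank$vectors)
#' @export
synthetic_feature_bank <- function(n_images = 8L, dim = 64L, sparsity = 0.8,
                                   overlap = 0.2, seed = NULL) {
  n_images <- as.integer(n_images)
  dim <- as.integer(dim)
  if (n_images < 1L || dim < 1L) stop_param("n_images and dim must be >= 1")
  check_scalar(sparsity, "sparsity", lower = 0, upper = 1, strict_upper = TRUE)
  check_scalar(overlap, "overlap", lower = 0, upper = 1)
  with_seed(seed, {
    draw <- function(n) {
      ifelse(stats::runif(n) < sparsity, 0, stats::runif(n, 0.2, 1.2))
    }
    template <- draw(dim)
    vectors <- matrix(0, n_images, dim)
    for (i in seq_len(n_images)) {
      own <- draw(dim)
      use_template <- stats::runif(dim) < overlap
      vectors[i, ] <- ifelse(use_template, template, own)
      if (all(vectors[i, ] == 0)) {
        vectors[i, sample.int(dim, 1L)] <- stats::runif(1, 0.2, 1.2)
      }
    }
    feature_bank(vectors, "synthetic",
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  })
}

#' Write / read a feature bank as CSV
#'
#' @param bank A [feature_bank()].
#' @param file Path to a CSV file.
#' @return `bank_to_csv` returns `file` invisibly; `bank_from_csv` returns
#'   the reconstructed bank (provenance is stored in a comment-free extra
#'   column).
#' @export
bank_to_csv <- function(bank, file) {
  stopifnot(inherits(bank, "feature_bank"))
  df <- as.data.frame(bank$vectors)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$provenance <- bank$provenance
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname bank_to_csv
#' @export
bank_from_csv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  prov <- as.character(df$provenance[1])
  df$provenance <- NULL
  feature_bank(as.matrix(df), prov)
}
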