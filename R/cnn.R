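# Minimal convolutional encoder implemented in base R. The network exists
# only to produce sparse nonnegative FC-64 feature vectors for the
# dynamic-synapse models, so it stays small: two same-padded convolution
# stages each followed by 2x2/stride-2 max pooling, one fully connected
# stage, the 64-unit rectified feature layer, and a class-score layer
# trained with softmax cross-entropy under plain SGD.

#' Configuration of the image encoder
#'
#' @param input_size `c(height, width)` of the grayscale inputs; both must
#'   be divisible by 4 (two pooling stages). Default `c(16, 16)`.
#' @param conv_channels Channel counts of the two convolution stages.
#'   Default `c(4, 8)`.
#' @param kernel_sizes Odd kernel sizes of the two stages. Default `c(5, 3)`.
#' @param fc_hidden Width of the fully connected stage before the feature
#'   layer. Default 64.
#' @param feature_dim Width of the rectified feature layer; fixed at 64 to
#'   match the dynamic-synapse input layer.
#' @param n_classes Number of image classes.
#' @param n_epochs,batch_size,lr,momentum SGD training settings.
#' @param seed Integer seed for weight initialization and batch order.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(input_size = c(16L, 16L), conv_channels = c(4L, 8L),
                           kernel_sizes = c(5L, 3L), fc_hidden = 64L,
                           feature_dim = 64L, n_classes = 2L,
                           n_epochs = 20L, batch_size = 16L,
                           lr = 0.01, momentum = 0.9, seed = 1L) {
  input_size <- as.integer(input_size)
  if (length(input_size) != 2L || any(input_size %% 4L != 0L)) {
    stop_param("input_size must be two dimensions divisible by 4")
  }
  if (length(conv_channels) != 2L || length(kernel_sizes) != 2L) {
    stop_param("exactly two convolution stages are supported")
  }
  if (any(kernel_sizes %% 2L == 0L)) stop_param("kernel sizes must be odd")
  if (as.integer(feature_dim) != 64L) {
    stop_param("feature_dim is fixed at 64 (the synapse input width)")
  }
  structure(
    list(input_size = input_size,
         conv_channels = as.integer(conv_channels),
         kernel_sizes = as.integer(kernel_sizes),
         fc_hidden = as.integer(fc_hidden), feature_dim = 64L,
         n_classes = as.integer(n_classes),
         n_epochs = as.integer(n_epochs),
         batch_size = as.integer(batch_size),
         lr = lr, momentum = momentum, seed = as.integer(seed)),
    class = "encoder_config"
  )
}

# im2col index map for same-padding stride-1 convolution on one padded
# image of channel depth c_in: rows = output positions, cols = patch taps.
conv_index_map <- function(h, w, k, c_in) {
  p <- (k - 1L) %/% 2L
  hp <- h + 2L * p
  wp <- w + 2L * p
  oi <- rep(seq_len(h), times = w)
  oj <- rep(seq_len(w), each = h)
  idx <- matrix(0L, h * w, k * k * c_in)
  col <- 0L
  for (ci in seq_len(c_in)) {
    chan_off <- (ci - 1L) * hp * wp
    for (dj in seq_len(k)) {
      for (di in seq_len(k)) {
        col <- col + 1L
        idx[, col] <- chan_off + (oj + dj - 2L) * hp + (oi + di - 1L)
      }
    }
  }
  list(idx = idx, hp = hp, wp = wp, p = p)
}

pad_image <- function(x, p) {
  # x: (h, w, c) array -> zero-padded (h+2p, w+2p, c)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  out
}

conv_forward <- function(x, wmat, b, map) {
  # x: padded image vector; returns list(out = (h*w) x c_out, cols)
  cols <- matrix(x[map$idx], nrow(map$idx), ncol(map$idx))
  list(out = sweep(cols %*% wmat, 2L, b, `+`), cols = cols)
}

conv_backward <- function(dout, cols, wmat, map, npix) {
  # returns gradient w.r.t. padded input vector, weights, bias
  dw <- crossprod(cols, dout)
  db <- colSums(dout)
  dcols <- dout %*% t(wmat)
  dx <- numeric(npix)
  for (cc in seq_len(ncol(dcols))) {
    tgt <- map$idx[, cc]
    dx[tgt] <- dx[tgt] + dcols[, cc]
  }
  list(dx = dx, dw = dw, db = db)
}

maxpool_forward <- function(x) {
  # x: (h, w, c) with even h, w -> list(out = (h/2, w/2, c), which)
  h <- dim(x)[1]; w <- dim(x)[2]
  a <- x[seq(1L, h, 2L), seq(1L, w, 2L), , drop = FALSE]
  b <- x[seq(2L, h, 2L), seq(1L, w, 2L), , drop = FALSE]
  cc <- x[seq(1L, h, 2L), seq(2L, w, 2L), , drop = FALSE]
  d <- x[seq(2L, h, 2L), seq(2L, w, 2L), , drop = FALSE]
  stacked <- cbind(as.vector(a), as.vector(b), as.vector(cc), as.vector(d))
  which_max <- max.col(stacked, ties.method = "first")
  out <- stacked[cbind(seq_len(nrow(stacked)), which_max)]
  list(out = array(out, dim(a)), which = which_max, in_dim = dim(x))
}

maxpool_backward <- function(dout, pool) {
  h <- pool$in_dim[1]; w <- pool$in_dim[2]
  dx <- array(0, pool$in_dim)
  dv <- as.vector(dout)
  n <- length(dv)
  qa <- qb <- qc <- qd <- numeric(n)
  qa[pool$which == 1L] <- dv[pool$which == 1L]
  qb[pool$which == 2L] <- dv[pool$which == 2L]
  qc[pool$which == 3L] <- dv[pool$which == 3L]
  qd[pool$which == 4L] <- dv[pool$which == 4L]
  dm <- dim(dout)
  dx[seq(1L, h, 2L), seq(1L, w, 2L), ] <- array(qa, dm)
  dx[seq(2L, h, 2L), seq(1L, w, 2L), ] <- array(qb, dm)
  dx[seq(1L, h, 2L), seq(2L, w, 2L), ] <- array(qc, dm)
  dx[seq(2L, h, 2L), seq(2L, w, 2L), ] <- array(qd, dm)
  dx
}

init_encoder_weights <- function(config) {
  k1 <- config$kernel_sizes[1]; k2 <- config$kernel_sizes[2]
  c1 <- config$conv_channels[1]; c2 <- config$conv_channels[2]
  h <- config$input_size[1]; w <- config$input_size[2]
  flat <- (h %/% 4L) * (w %/% 4L) * c2
  he <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))
  list(
    w1 = matrix(he(k1 * k1, k1 * k1 * 1L * c1), k1 * k1, c1),
    b1 = numeric(c1),
    w2 = matrix(he(k2 * k2 * c1, k2 * k2 * c1 * c2), k2 * k2 * c1, c2),
    b2 = numeric(c2),
    w3 = matrix(he(flat, flat * config$fc_hidden), flat, config$fc_hidden),
    b3 = numeric(config$fc_hidden),
    w4 = matrix(he(config$fc_hidden, config$fc_hidden * 64L),
                config$fc_hidden, 64L),
    b4 = numeric(64L),
    w5 = matrix(he(64L, 64L * config$n_classes), 64L, config$n_classes),
    b5 = numeric(config$n_classes)
  )
}

check_images <- function(images, config) {
  if (length(dim(images)) != 3L) {
    stop_param("images must be a (height, width, n) grayscale array")
  }
  if (!all(dim(images)[1:2] == config$input_size)) {
    stop_param("image size ", paste(dim(images)[1:2], collapse = "x"),
               " does not match configured ",
               paste(config$input_size, collapse = "x"))
  }
  if (any(!is.finite(images))) stop_param("images contain non-finite values")
  invisible(images)
}

# Full forward pass for one image; returns all intermediates when
# keep = TRUE (training) or just features / class scores otherwise.
encoder_forward_one <- function(img, wts, config, maps, keep = FALSE) {
  h <- config$input_size[1]; w <- config$input_size[2]
  x0 <- array(img, c(h, w, 1L))
  xp1 <- pad_image(x0, maps$m1$p)
  cv1 <- conv_forward(as.vector(xp1), wts$w1, wts$b1, maps$m1)
  a1 <- relu(cv1$out)
  p1 <- maxpool_forward(array(a1, c(h, w, config$conv_channels[1])))
  h2 <- h %/% 2L; w2 <- w %/% 2L
  xp2 <- pad_image(p1$out, maps$m2$p)
  cv2 <- conv_forward(as.vector(xp2), wts$w2, wts$b2, maps$m2)
  a2 <- relu(cv2$out)
  p2 <- maxpool_forward(array(a2, c(h2, w2, config$conv_channels[2])))
  flat <- as.vector(p2$out)
  z3 <- as.vector(flat %*% wts$w3) + wts$b3
  a3 <- relu(z3)
  z4 <- as.vector(a3 %*% wts$w4) + wts$b4
  feat <- relu(z4)
  scores <- as.vector(feat %*% wts$w5) + wts$b5
  if (!keep) return(list(features = feat, scores = scores))
  list(features = feat, scores = scores, flat = flat, a3 = a3, z3 = z3,
       z4 = z4, cv1 = cv1, cv2 = cv2, p1 = p1, p2 = p2,
       a1 = a1, a2 = a2)
}

encoder_backward_one <- function(dscores, fw, wts, config, maps) {
  h <- config$input_size[1]; w <- config$input_size[2]
  g <- list()
  g$w5 <- outer(fw$features, dscores)
  g$b5 <- dscores
  dfeat <- as.vector(wts$w5 %*% dscores)
  dz4 <- dfeat * (fw$z4 > 0)
  g$w4 <- outer(fw$a3, dz4)
  g$b4 <- dz4
  da3 <- as.vector(wts$w4 %*% dz4)
  dz3 <- da3 * (fw$z3 > 0)
  g$w3 <- outer(fw$flat, dz3)
  g$b3 <- dz3
  dflat <- as.vector(wts$w3 %*% dz3)
  h4 <- h %/% 4L; w4d <- w %/% 4L
  dp2 <- array(dflat, c(h4, w4d, config$conv_channels[2]))
  da2 <- maxpool_backward(dp2, fw$p2)
  dz2 <- as.vector(da2) * (as.vector(fw$cv2$out) > 0)
  dz2 <- matrix(dz2, nrow(fw$cv2$out), ncol(fw$cv2$out))
  npix2 <- maps$m2$hp * maps$m2$wp * config$conv_channels[1]
  cb2 <- conv_backward(dz2, fw$cv2$cols, wts$w2, maps$m2, npix2)
  g$w2 <- cb2$dw; g$b2 <- cb2$db
  h2 <- h %/% 2L; w2d <- w %/% 2L
  dxp2 <- array(cb2$dx, c(maps$m2$hp, maps$m2$wp, config$conv_channels[1]))
  dp1 <- dxp2[maps$m2$p + seq_len(h2), maps$m2$p + seq_len(w2d), ,
              drop = FALSE]
  da1 <- maxpool_backward(dp1, fw$p1)
  dz1 <- as.vector(da1) * (as.vector(fw$cv1$out) > 0)
  dz1 <- matrix(dz1, nrow(fw$cv1$out), ncol(fw$cv1$out))
  npix1 <- maps$m1$hp * maps$m1$wp * 1L
  cb1 <- conv_backward(dz1, fw$cv1$cols, wts$w1, maps$m1, npix1)
  g$w1 <- cb1$dw; g$b1 <- cb1$db
  g
}

encoder_maps <- function(config) {
  h <- config$input_size[1]; w <- config$input_size[2]
  list(
    m1 = conv_index_map(h, w, config$kernel_sizes[1], 1L),
    m2 = conv_index_map(h %/% 2L, w %/% 2L, config$kernel_sizes[2],
                        config$conv_channels[1])
  )
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Train the convolutional image encoder
#'
#' Trains the small CNN of [encoder_config()] with stochastic gradient
#' descent on softmax cross-entropy. Intended for small synthetic image
#' sets; the encoder exists only to provide a 64-dimensional rectified
#' feature bank, not to pursue classification benchmarks.
#'
#' @param images `(height, width, n)` array of grayscale images.
#' @param labels Integer class labels in `1..n_classes`.
#' @param config An [encoder_config()].
#' @return An object of class `image_encoder` with the trained weights,
#'   the per-epoch loss history and the final training accuracy.
#' @export
train_encoder <- function(images, labels, config) {
  stopifnot(inherits(config, "encoder_config"))
  check_images(images, config)
  labels <- as.integer(labels)
  n <- dim(images)[3]
  if (length(labels) != n) stop_param("one label per image required")
  if (any(labels < 1L | labels > config$n_classes)) {
    stop_param("labels must lie in 1..n_classes")
  }
  maps <- encoder_maps(config)
  with_seed(config$seed, {
    wts <- init_encoder_weights(config)
    vel <- lapply(wts, function(w) w * 0)
    loss_history <- numeric(config$n_epochs)
    for (epoch in seq_len(config$n_epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        grads <- NULL
        batch_loss <- 0
        for (i in idx) {
          fw <- encoder_forward_one(images[, , i], wts, config, maps,
                                    keep = TRUE)
          p <- softmax(fw$scores)
          batch_loss <- batch_loss - log(max(p[labels[i]], 1e-12))
          dscores <- p
          dscores[labels[i]] <- dscores[labels[i]] - 1
          g <- encoder_backward_one(dscores / length(idx), fw, wts,
                                    config, maps)
          grads <- if (is.null(grads)) g else Map(`+`, grads, g)
        }
        for (nm in names(wts)) {
          vel[[nm]] <- config$momentum * vel[[nm]] - config$lr * grads[[nm]]
          wts[[nm]] <- wts[[nm]] + vel[[nm]]
        }
        epoch_loss <- epoch_loss + batch_loss
      }
      loss_history[epoch] <- epoch_loss / n
    }
    enc <- structure(
      list(config = config, weights = wts, loss_history = loss_history,
           final_loss = loss_history[config$n_epochs], trained = TRUE),
      class = "image_encoder"
    )
    enc$train_accuracy <- mean(predict_classes(enc, images) == labels)
    enc
  })
}

#' @export
print.image_encoder <- function(x, ...) {
  cat(sprintf(
    "Image encoder: %dx%d -> conv%d-%d -> conv%d-%d -> FC-%d -> FC-64 -> %d classes\n",
    x$config$input_size[1], x$config$input_size[2],
    x$config$kernel_sizes[1], x$config$conv_channels[1],
    x$config$kernel_sizes[2], x$config$conv_channels[2],
    x$config$fc_hidden, x$config$n_classes))
  cat(sprintf("  final loss %.4f, training accuracy %.3f\n",
              x$final_loss, x$train_accuracy))
  invisible(x)
}

#' Class probabilities and predicted classes for images
#'
#' @param encoder A trained [train_encoder()] result.
#' @param images `(height, width, n)` grayscale array.
#' @return `predict_probs`: an `n x n_classes` matrix of softmax
#'   probabilities (rows sum to 1); `predict_classes`: integer labels.
#' @export
predict_probs <- function(encoder, images) {
  stopifnot(inherits(encoder, "image_encoder"))
  check_images(images, encoder$config)
  maps <- encoder_maps(encoder$config)
  n <- dim(images)[3]
  out <- matrix(NA_real_, n, encoder$config$n_classes)
  for (i in seq_len(n)) {
    fw <- encoder_forward_one(images[, , i], encoder$weights,
                              encoder$config, maps)
    out[i, ] <- softmax(fw$scores)
  }
  out
}

#' @rdname predict_probs
#' @export
predict_classes <- function(encoder, images) {
  max.col(predict_probs(encoder, images), ties.method = "first")
}

#' Extract the FC-64 feature bank from a trained encoder
#'
#' Returns the rectified activations of the 64-unit layer preceding the
#' classifier, one row per image — the presynaptic drive vectors of the
#' dynamic-synapse models.
#'
#' @param encoder A trained [train_encoder()] result.
#' @param images `(height, width, n)` grayscale array.
#' @return A [feature_bank()] with provenance `"trained-encoder"`.
#' @export
extract_features <- function(encoder, images) {
  stopifnot(inherits(encoder, "image_encoder"))
  if (!isTRUE(encoder$trained)) stop_param("encoder has not been trained")
  check_images(images, encoder$config)
  maps <- encoder_maps(encoder$config)
  n <- dim(images)[3]
  feats <- matrix(NA_real_, n, 64L)
  for (i in seq_len(n)) {
    fw <- encoder_forward_one(images[, , i], encoder$weights,
                              encoder$config, maps)
    feats[i, ] <- fw$features
  }
  feature_bank(feats, "trained-encoder", seed = encoder$config$seed)
}

#' Persist and reload an encoder
#'
#' Weights round-trip bit-exactly, so saved and reloaded encoders produce
#' identical features.
#'
#' @param encoder A trained encoder.
#' @param file Path to write to / read from.
#' @return `load_encoder` returns the encoder.
#' @export
save_encoder <- function(encoder, file) {
  stopifnot(inherits(encoder, "image_encoder"))
  saveRDS(encoder, file)
  invisible(file)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(file) {
  enc <- readRDS(file)
  stopifnot(inherits(enc, "image_encoder"))
  enc
}

#' Generate a synthetic grayscale image set
#'
#' Produces class-separable toy images without any dataset dependency.
#' Each class is a bright Gaussian blob at a class-specific location on a
#' dark background (for two classes: bright-left versus bright-right),
#' plus i.i.d. pixel noise, clipped to \[0, 1\].
#'
#' @param n_per_class Images per class.
#' @param n_classes Number of classes (default 2).
#' @param size `c(height, width)` (default `c(16, 16)`).
#' @param noise Standard deviation of additive pixel noise. Default 0.1.
#' @param seed Optional integer seed.
#' @return List with `images` (`(h, w, n)` array) and `labels`.
#' @export
synthetic_image_set <- function(n_per_class, n_classes = 2L,
                                size = c(16L, 16L), noise = 0.1,
                                seed = NULL) {
  with_seed(seed, {
    h <- size[1]; w <- size[2]
    n <- n_per_class * n_classes
    images <- array(0, c(h, w, n))
    labels <- rep(seq_len(n_classes), each = n_per_class)
    angles <- 2 * pi * (seq_len(n_classes) - 1L) / n_classes
    cy <- h / 2 + (h / 4) * sin(angles)
    cx <- w / 2 + (w / 4) * cos(angles)
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (i in seq_len(n)) {
      k <- labels[i]
      blob <- exp(-((yy - cy[k])^2 + (xx - cx[k])^2) / (2 * (h / 5)^2))
      img <- 0.1 + 0.8 * blob + stats::rnorm(h * w, 0, noise)
      images[, , i] <- pmin(pmax(img, 0), 1)
    }
    list(images = images, labels = labels)
  })
}
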