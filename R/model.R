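#' Classifier architecture specification
#'
#' Two spatio-temporal video classifiers are available:
#' \describe{
#'   \item{`"3dcnn"`}{six 3D convolutional layers (3x3x3, stride 1, same
#'     padding, ReLU) with four interleaved 2x max-pooling layers, followed
#'     by two fully-connected layers (widths `fc_hidden`, then `n_classes`)
#'     and a softmax.}
#'   \item{`"lrcn"`}{a per-frame 2D feature extractor of six convolutional
#'     layers and three pooling layers whose vectorised output feeds an LSTM;
#'     the class prediction is read from the final LSTM step.}
#' }
#' Filter counts, kernel sizes and the LSTM width are configurable; the
#' `"tiny"` preset shrinks all widths for desk-scale experiments.
#'
#' @param architecture `"3dcnn"` or `"lrcn"`.
#' @param input_shape Integer (height, width, n_frames) of the (cropped,
#'   normalised) input sequences.
#' @param n_classes 2 (good vs artefact) or 3 (good/breathing/mistriggering).
#' @param conv_channels Six per-layer filter counts.
#' @param lstm_hidden LSTM hidden width (LRCN only).
#' @param fc_hidden Width of the first fully-connected layer (3D-CNN only).
#' @param dropout_rate Dropout probability applied after every convolutional
#'   block and after the first fully-connected layer / LSTM output.
#' @param init `"he"` (Gaussian, sd = sqrt(2/fan_in)) or `"unit"` (Gaussian,
#'   sd = 1).
#' @param preset `"tiny"` overrides the widths with desk-scale defaults.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(architecture = c("3dcnn", "lrcn"),
                       input_shape = c(80L, 80L, 50L), n_classes = 2L,
                       conv_channels = c(16L, 32L, 32L, 64L, 64L, 128L),
                       lstm_hidden = 128L, fc_hidden = 1024L,
                       dropout_rate = 0.5, init = c("he", "unit"),
                       preset = NULL) {
  architecture <- match.arg(architecture)
  init <- match.arg(init)
  if (!is.null(preset)) {
    if (!identical(preset, "tiny")) stop_invariant("unknown preset '%s'", preset)
    if (missing(conv_channels)) conv_channels <- c(2L, 2L, 4L, 4L, 8L, 8L)
    if (missing(lstm_hidden)) lstm_hidden <- 16L
    if (missing(fc_hidden)) fc_hidden <- 32L
  }
  if (length(conv_channels) != 6L) {
    stop_invariant("`conv_channels` must list 6 filter counts (6 convolutional layers)")
  }
  if (!n_classes %in% c(2L, 3L)) stop_invariant("`n_classes` must be 2 or 3")
  if (length(input_shape) != 3L || any(input_shape < 1)) {
    stop_invariant("`input_shape` must be (height, width, n_frames)")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_invariant("`dropout_rate` must be in [0, 1)")
  }
  structure(list(architecture = architecture,
                 input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes),
                 conv_channels = as.integer(conv_channels),
                 lstm_hidden = as.integer(lstm_hidden),
                 fc_hidden = as.integer(fc_hidden),
                 dropout_rate = dropout_rate, init = init,
                 preset = preset),
            class = "model_spec")
}

# Pooling positions: 3dcnn pools after convs 1,2,4,6 (4 pools);
# lrcn extractor pools after convs 1,2,4 (3 pools).
arch_pool_after <- function(architecture) {
  if (architecture == "3dcnn") c(1L, 2L, 4L, 6L) else c(1L, 2L, 4L)
}

pooled_dim <- function(n, times) {
  for (i in seq_len(times)) n <- if (n >= 2L) n %/% 2L else n
  n
}

#' Build a randomly initialised model
#'
#' Weights are drawn from a zero-mean Gaussian whose standard deviation is
#' set by `spec$init`; building is deterministic given the seed.
#'
#' @param spec A [model_spec()].
#' @param seed RNG seed for the weight draw.
#' @return An object of class `model_state` with fields `spec`, `layers`,
#'   and (after training) `training_log`.
#' @export
build_model <- function(spec, seed = 1L) {
  if (!inherits(spec, "model_spec")) stop_invariant("`spec` must be a `model_spec`")
  h <- spec$input_shape[1]; w <- spec$input_shape[2]; tt <- spec$input_shape[3]
  ch <- spec$conv_channels
  pool_after <- arch_pool_after(spec$architecture)

  with_seed(seed, {
    layers <- list()
    cin <- 1L
    for (i in seq_len(6L)) {
      layers[[length(layers) + 1L]] <-
        if (spec$architecture == "3dcnn") {
          conv3_layer(cin, ch[i], init = spec$init)
        } else {
          conv2_layer(cin, ch[i], init = spec$init)
        }
      if (i %in% pool_after) {
        layers[[length(layers) + 1L]] <-
          list(type = if (spec$architecture == "3dcnn") "pool3" else "pool2")
      }
      layers[[length(layers) + 1L]] <- list(type = "dropout",
                                            rate = spec$dropout_rate)
      cin <- ch[i]
    }
    np <- length(pool_after)
    hp <- pooled_dim(h, np); wp <- pooled_dim(w, np)
    if (hp < 1L || wp < 1L) {
      stop_invariant("input %d x %d too small for %d pooling layers", h, w, np)
    }
    if (spec$architecture == "3dcnn") {
      tp <- pooled_dim(tt, np)
      feat <- hp * wp * tp * ch[6]
      layers[[length(layers) + 1L]] <- list(type = "flatten")
      layers[[length(layers) + 1L]] <- dense_layer(feat, spec$fc_hidden,
                                                   init = spec$init, relu = TRUE)
      layers[[length(layers) + 1L]] <- list(type = "dropout",
                                            rate = spec$dropout_rate)
      layers[[length(layers) + 1L]] <- dense_layer(spec$fc_hidden, spec$n_classes,
                                                   init = spec$init)
    } else {
      feat <- hp * wp * ch[6]
      layers[[length(layers) + 1L]] <- list(type = "flatten")
      layers[[length(layers) + 1L]] <- lstm_layer(feat, spec$lstm_hidden,
                                                  init = spec$init)
      layers[[length(layers) + 1L]] <- list(type = "dropout",
                                            rate = spec$dropout_rate)
      layers[[length(layers) + 1L]] <- dense_layer(spec$lstm_hidden,
                                                   spec$n_classes,
                                                   init = spec$init)
    }
    structure(list(spec = spec, layers = layers, training_log = NULL),
              class = "model_state")
  })
}

#' @export
print.model_state <- function(x, ...) {
  cat(sprintf("<model_state> %s, input %s, %d classes\n", x$spec$architecture,
              paste(x$spec$input_shape, collapse = "x"), x$spec$n_classes))
  cat(sprintf("  %d layers, %d trainable parameters\n", length(x$layers),
              n_parameters(x)))
  if (!is.null(x$training_log)) {
    cat(sprintf("  trained: %d epochs logged\n", nrow(x$training_log)))
  }
  invisible(x)
}

n_parameters <- function(state) {
  sum(vapply(state$layers, function(l) {
    length(l$W %||% numeric(0)) + length(l$b %||% numeric(0)) +
      length(l$Wx %||% numeric(0)) + length(l$Wh %||% numeric(0))
  }, 0))
}

# x: (H, W, T, N) batch array. Returns list(logits, caches).
model_forward <- function(state, x, train = FALSE) {
  spec <- state$spec
  d <- dim(x)
  if (!identical(as.integer(d[1:3]), spec$input_shape)) {
    stop_invariant("input shape (%s) does not match spec (%s)",
                   paste(d[1:3], collapse = "x"),
                   paste(spec$input_shape, collapse = "x"))
  }
  N <- d[4]
  caches <- vector("list", length(state$layers))
  if (spec$architecture == "3dcnn") {
    a <- array(x, c(d[1], d[2], d[3], 1L, N))
    cur <- a
    for (li in seq_along(state$layers)) {
      l <- state$layers[[li]]
      r <- switch(l$type,
        conv3 = conv3_forward(l, cur, train),
        pool3 = pool_forward(cur, 3L),
        dropout = dropout_forward(cur, l$rate, train),
        flatten = {
          dd <- dim(cur)
          list(out = t(matrix(cur, prod(dd[-length(dd)]), dd[length(dd)])),
               cache = dd)
        },
        dense = dense_forward(l, cur, train),
        stop_invariant("unknown layer type '%s'", l$type))
      cur <- r$out; caches[[li]] <- r$cache
    }
    list(logits = cur, caches = caches)
  } else {
    Tn <- d[3]
    frames <- array(x, c(d[1], d[2], 1L, Tn * N))  # frame m = t + (n-1)*T
    cur <- frames
    for (li in seq_along(state$layers)) {
      l <- state$layers[[li]]
      r <- switch(l$type,
        conv2 = conv2_forward(l, cur, train),
        pool2 = pool_forward(cur, 2L),
        dropout = dropout_forward(cur, l$rate, train),
        flatten = {
          dd <- dim(cur)
          feat <- t(matrix(cur, prod(dd[-length(dd)]), dd[length(dd)]))
          list(out = feat, cache = dd)
        },
        lstm = {
          xs <- lapply(seq_len(Tn), function(t) {
            cur[t + Tn * (0:(N - 1L)), , drop = FALSE]
          })
          lstm_forward(l, xs, train)
        },
        dense = dense_forward(l, cur, train),
        stop_invariant("unknown layer type '%s'", l$type))
      cur <- r$out; caches[[li]] <- r$cache
    }
    list(logits = cur, caches = caches)
  }
}

# Returns a list of per-layer gradients (NULL for parameter-free layers).
model_backward <- function(state, caches, dlogits, batch_dims) {
  spec <- state$spec
  grads <- vector("list", length(state$layers))
  cur <- dlogits
  Tn <- batch_dims[3]; N <- batch_dims[4]
  for (li in rev(seq_along(state$layers))) {
    l <- state$layers[[li]]
    if (l$type %in% c("conv2", "conv3")) {
      r <- if (l$type == "conv2") conv2_backward(l, cur, caches[[li]])
           else conv3_backward(l, cur, caches[[li]])
      grads[[li]] <- list(W = r$dW, b = r$db)
      cur <- r$dx
    } else if (l$type %in% c("pool2", "pool3")) {
      cur <- pool_backward(cur, caches[[li]])
    } else if (l$type == "dropout") {
      cur <- dropout_backward(cur, caches[[li]])
    } else if (l$type == "flatten") {
      dd <- caches[[li]]
      cur <- array(t(cur), dd)
    } else if (l$type == "dense") {
      r <- dense_backward(l, cur, caches[[li]])
      grads[[li]] <- list(W = r$dW, b = r$db)
      cur <- r$dx
    } else if (l$type == "lstm") {
      r <- lstm_backward(l, cur, caches[[li]])
      grads[[li]] <- list(Wx = r$dWx, Wh = r$dWh, b = r$db)
      feat_dim <- ncol(r$dxs[[1]])
      dfeat <- matrix(0, Tn * N, feat_dim)
      for (t in seq_len(Tn)) dfeat[t + Tn * (0:(N - 1L)), ] <- r$dxs[[t]]
      cur <- dfeat
    } else {
      stop_invariant("unknown layer type '%s'", l$type)
    }
  }
  grads
}

#' Predict class probabilities for cine sequences
#'
#' Runs the model in evaluation mode (dropout disabled). Probabilities sum to
#' one per sequence (softmax output).
#'
#' @param object A trained (or freshly built) `model_state`.
#' @param newdata A [cine_sequence()], a list of them, or an array of
#'   dimension (height, width, n_frames, n_sequences) matching the spec's
#'   `input_shape`.
#' @param ... Unused.
#' @return A numeric matrix (n_sequences x n_classes) of class probabilities.
#' @export
predict.model_state <- function(object, newdata, ...) {
  x <- as_input_array(newdata, object$spec$input_shape)
  fw <- model_forward(object, x, train = FALSE)
  softmax(fw$logits)
}

as_input_array <- function(newdata, input_shape) {
  if (inherits(newdata, "cine_sequence")) newdata <- list(newdata)
  if (is.list(newdata)) {
    arrs <- lapply(newdata, function(s) {
      assert_cine(s)
      s$frames
    })
    x <- array(0, c(input_shape, length(arrs)))
    for (i in seq_along(arrs)) {
      if (!identical(as.integer(dim(arrs[[i]])), input_shape)) {
        stop_invariant("sequence %d has shape (%s), spec expects (%s)", i,
                       paste(dim(arrs[[i]]), collapse = "x"),
                       paste(input_shape, collapse = "x"))
      }
      x[, , , i] <- arrs[[i]]
    }
    x
  } else if (is.array(newdata) && length(dim(newdata)) == 4L) {
    if (!identical(as.integer(dim(newdata)[1:3]), input_shape)) {
      stop_invariant("array shape (%s) does not match spec input (%s)",
                     paste(dim(newdata)[1:3], collapse = "x"),
                     paste(input_shape, collapse = "x"))
    }
    newdata
  } else {
    stop_invariant("`newdata` must be cine sequence(s) or a 4D array")
  }
}

#' Binary cross-entropy loss
#'
#' `L = -(1/n) * sum(y*log(p) + (1-y)*log(1-p))` with predictions clipped to
#' `[eps, 1-eps]`. The weighted variant multiplies each term by its class
#' weight; weights of 1 reduce exactly to the unweighted loss.
#'
#' @param y True labels in {0, 1}.
#' @param y_hat Predicted probabilities of class 1.
#' @param class_weights Optional length-2 numeric `(w0, w1)`.
#' @param eps Clipping constant.
#' @return Non-negative scalar loss.
#' @export
binary_cross_entropy <- function(y, y_hat, class_weights = NULL, eps = 1e-7) {
  if (length(y) != length(y_hat)) {
    stop_invariant("`y` and `y_hat` lengths differ (%d vs %d)",
                   length(y), length(y_hat))
  }
  if (!all(y %in% c(0, 1))) stop_invariant("`y` must contain only 0 and 1")
  p <- clamp(y_hat, eps, 1 - eps)
  w <- if (is.null(class_weights)) rep(1, length(y)) else class_weights[y + 1L]
  -mean(w * (y * log(p) + (1 - y) * log(1 - p)))
}
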