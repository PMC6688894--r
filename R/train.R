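#' Training configuration
#'
#' Defaults follow a standard cine-QC training recipe: SGD with momentum
#' 0.90, learning rate 1e-4, batches of 50 sequences, early stopping when
#' validation balanced accuracy fails to improve by at least 0.5% (relative)
#' for 100 consecutive epochs.
#'
#' @param batch_size Sequences per SGD step.
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum in [0, 1).
#' @param epochs Maximum number of epochs.
#' @param epochs_per_stage Epochs per curriculum stage (`k` in the baby-step
#'   scheme).
#' @param patience Epochs without sufficient improvement before stopping;
#'   `patience = 0` stops after the first epoch, `Inf` disables early
#'   stopping.
#' @param min_rel_improvement Relative validation gain counted as progress.
#' @param class_weights Optional per-class loss weights (first element =
#'   class 0 = good).
#' @param seed RNG seed for shuffling, dropout and any augmentation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 50L, learning_rate = 1e-4,
                         momentum = 0.90, epochs = 200L,
                         epochs_per_stage = 10L, patience = 100,
                         min_rel_improvement = 0.005, class_weights = NULL,
                         seed = 1L) {
  if (!is_count(batch_size, 1L)) stop_invariant("`batch_size` must be >= 1")
  if (learning_rate <= 0) stop_invariant("`learning_rate` must be > 0")
  if (momentum < 0 || momentum >= 1) stop_invariant("`momentum` must be in [0, 1)")
  if (min_rel_improvement <= 0 || min_rel_improvement >= 1) {
    stop_invariant("`min_rel_improvement` must be in (0, 1)")
  }
  if (!(is_count(patience) || is.infinite(patience))) {
    stop_invariant("`patience` must be a non-negative integer or Inf")
  }
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs),
                 epochs_per_stage = as.integer(epochs_per_stage),
                 patience = patience,
                 min_rel_improvement = min_rel_improvement,
                 class_weights = class_weights, seed = seed),
            class = "train_config")
}

#' Assemble a training set from labelled cine sequences
#'
#' Stacks sequences into a 4D array and encodes labels as 0-based integers
#' (`"good"` is always class 0; artefact classes follow `label_levels`
#' order).
#'
#' @param seqs List of [cine_sequence()] objects with labels set.
#' @param label_levels Character vector of class labels, class 0 first.
#' @param ids Optional sample identifiers (default `seq_1`, ...).
#' @return A list with fields `x` (H x W x T x N array), `y` (integer),
#'   `ids`, `label_levels`.
#' @export
as_training_set <- function(seqs, label_levels = NULL, ids = NULL) {
  if (!length(seqs)) stop_invariant("empty sequence list")
  labels <- vapply(seqs, function(s) s$label, "")
  if (anyNA(labels)) stop_invariant("all sequences must be labelled")
  if (is.null(label_levels)) {
    others <- sort(setdiff(unique(labels), "good"))
    label_levels <- c("good", others)
  }
  if (!all(labels %in% label_levels)) {
    stop_invariant("labels {%s} outside label_levels {%s}",
                   paste(setdiff(labels, label_levels), collapse = ","),
                   paste(label_levels, collapse = ","))
  }
  d <- dim(seqs[[1]]$frames)
  x <- array(0, c(d, length(seqs)))
  for (i in seq_along(seqs)) x[, , , i] <- seqs[[i]]$frames
  list(x = x, y = as.integer(match(labels, label_levels) - 1L),
       ids = ids %||% paste0("seq_", seq_along(seqs)),
       label_levels = label_levels)
}

# Paper-variant balanced accuracy of hard predictions, used as the
# early-stopping / checkpoint-selection metric. Undefined components
# (empty denominators) count as 0 here so the metric is always comparable.
monitor_balanced_accuracy <- function(y_true, y_pred) {
  pos_true <- y_true > 0; pos_pred <- y_pred > 0
  tp <- sum(pos_true & pos_pred)
  fp <- sum(!pos_true & pos_pred)
  fn <- sum(pos_true & !pos_pred)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  (prec + rec) / 2
}

model_weights <- function(state) {
  lapply(state$layers, function(l) l[intersect(names(l), c("W", "b", "Wx", "Wh"))])
}

set_model_weights <- function(state, weights) {
  for (i in seq_along(weights)) {
    for (nm in names(weights[[i]])) state$layers[[i]][[nm]] <- weights[[i]][[nm]]
  }
  state
}

zero_velocity <- function(state) {
  lapply(state$layers, function(l) {
    nm <- intersect(names(l), c("W", "b", "Wx", "Wh"))
    stats::setNames(lapply(nm, function(n) l[[n]] * 0), nm)
  })
}

sgd_update <- function(state, grads, velocity, lr, momentum) {
  for (i in seq_along(grads)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      velocity[[i]][[nm]] <- momentum * velocity[[i]][[nm]] - lr * g[[nm]]
      state$layers[[i]][[nm]] <- state$layers[[i]][[nm]] + velocity[[i]][[nm]]
    }
  }
  list(state = state, velocity = velocity)
}

predict_classes <- function(state, x, batch = 64L) {
  n <- dim(x)[4]
  probs <- matrix(0, n, state$spec$n_classes)
  for (b0 in seq(1L, n, by = batch)) {
    idx <- b0:min(n, b0 + batch - 1L)
    fw <- model_forward(state, x[, , , idx, drop = FALSE], train = FALSE)
    probs[idx, ] <- softmax(fw$logits)
  }
  probs
}

#' Train a classifier with SGD + momentum and early stopping
#'
#' Minimises the (optionally class-weighted) cross entropy by stochastic
#' gradient descent with momentum. After every epoch the validation balanced
#' accuracy is computed; the returned model carries the weights of the best
#' validation epoch. Training stops when the number of consecutive epochs
#' without a sufficient relative improvement exceeds `config$patience`
#' (with `patience = 0`, exactly one epoch runs), or after `config$epochs`.
#'
#' @param state A `model_state` from [build_model()].
#' @param train_set,val_set Sets from [as_training_set()]; the training set
#'   must contain both classes unless `class_weights` overrides the check.
#' @param config A [train_config()].
#' @param log_batches If `TRUE`, record the sample ids of every minibatch in
#'   the training log (provenance for curriculum bookkeeping).
#' @return The trained `model_state`; `$training_log` is a data frame with
#'   one row per epoch (loss, training accuracy, validation balanced
#'   accuracy) and, if requested, a `batches` attribute.
#' @export
train <- function(state, train_set, val_set, config = train_config(),
                  log_batches = FALSE) {
  if (!inherits(state, "model_state")) stop_invariant("`state` must be a `model_state`")
  n <- length(train_set$y)
  if (n == 0L || length(val_set$y) == 0L) {
    stop_invariant("training and validation sets must be non-empty")
  }
  if (length(unique(train_set$y)) < 2L && is.null(config$class_weights)) {
    stop_invariant("single-class training set (class %d only); supply `class_weights` to override",
                   train_set$y[1])
  }

  with_seed(config$seed, {
    velocity <- zero_velocity(state)
    best_metric <- -Inf
    best_weights <- model_weights(state)
    best_epoch <- 0L
    stall <- 0L
    log <- data.frame(epoch = integer(), train_loss = numeric(),
                      train_acc = numeric(), val_balanced_accuracy = numeric(),
                      improved = logical())
    batch_log <- list()

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      correct <- 0L
      epoch_batches <- list()
      for (b0 in seq(1L, n, by = config$batch_size)) {
        idx <- ord[b0:min(n, b0 + config$batch_size - 1L)]
        xb <- train_set$x[, , , idx, drop = FALSE]
        yb <- train_set$y[idx]
        fw <- model_forward(state, xb, train = TRUE)
        ce <- softmax_ce(fw$logits, yb, weights = config$class_weights)
        grads <- model_backward(state, fw$caches, ce$dlogits, dim(xb))
        upd <- sgd_update(state, grads, velocity, config$learning_rate,
                          config$momentum)
        state <- upd$state; velocity <- upd$velocity
        losses <- c(losses, ce$loss)
        correct <- correct + sum(max.col(ce$probs) - 1L == yb)
        if (log_batches) epoch_batches[[length(epoch_batches) + 1L]] <- train_set$ids[idx]
      }
      val_prob <- predict_classes(state, val_set$x)
      val_pred <- max.col(val_prob) - 1L
      m <- monitor_balanced_accuracy(val_set$y, val_pred)

      improved <- is.finite(best_metric) &&
        (m >= best_metric + config$min_rel_improvement * max(abs(best_metric), 1e-8))
      if (m > best_metric) {
        best_metric <- m
        best_weights <- model_weights(state)
        best_epoch <- epoch
      }
      stall <- if (improved) 0L else stall + 1L
      log <- rbind(log, data.frame(epoch = epoch, train_loss = mean(losses),
                                   train_acc = correct / n,
                                   val_balanced_accuracy = m,
                                   improved = improved))
      if (log_batches) batch_log[[epoch]] <- epoch_batches
      if (stall > config$patience) break
    }

    state <- set_model_weights(state, best_weights)
    attr(log, "best_epoch") <- best_epoch
    attr(log, "best_metric") <- best_metric
    if (log_batches) attr(log, "batches") <- batch_log
    state$training_log <- log
    state
  })
}

#' Inverse-frequency class weights
#'
#' Weights proportional to the inverse class frequency, normalised so the
#' majority class has weight 1 (a 224:10 split yields weights 1 and 22.4).
#'
#' @param y Integer class labels (0-based).
#' @param n_classes Number of classes.
#' @return Numeric vector of per-class weights.
#' @export
inverse_class_weights <- function(y, n_classes = max(y) + 1L) {
  counts <- tabulate(y + 1L, nbins = n_classes)
  if (any(counts == 0L)) stop_invariant("every class must be present to weight by frequency")
  w <- 1 / counts
  w / min(w)
}
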