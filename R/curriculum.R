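#' Build a severity-ordered training curriculum
#'
#' Constructs the baby-step curriculum: `b` stages of freshly corrupted
#' copies of good-quality base samples, one stage per severity level. In
#' `"curriculum"` order, stage 1 holds the most severe (easiest to classify)
#' corruptions and stage `b` the least severe; `"anti"` reverses the stage
#' order; `"control"` pools all synthetic samples and splits them into `b`
#' equal stages by a seeded random permutation. The original data set —
#' including every original artefact-labelled sample — is kept alongside and
#' is part of the training pool at every stage.
#'
#' @param base_set List of labelled [cine_sequence()] objects (the "original"
#'   data set; its good-quality members are the corruption sources).
#' @param schedules Named list of [severity_schedule()]s (one per artefact
#'   type), all with the same number of levels `b`.
#' @param samples_per_stage Synthetic samples per stage (split evenly across
#'   artefact types).
#' @param order_mode `"curriculum"`, `"anti"` or `"control"`.
#' @param seed RNG seed for source sampling, corruption seeds and the control
#'   permutation.
#' @param source_set Optional list of sequences to corrupt (defaults to the
#'   good-quality members of `base_set`). Useful when corruption must happen
#'   at native image size while the training pool holds cropped/normalised
#'   versions.
#' @param postprocess Optional `function(corrupted, source_index)` applied to
#'   every synthetic sample (e.g. ROI cropping + intensity normalisation
#'   matching the base set's preprocessing).
#' @return An object of class `curriculum` with fields `stages` (list of
#'   lists of sequences), `stage_ids`, `original_set`, `original_ids`, `b`,
#'   `order_mode`.
#' @export
build_curriculum <- function(base_set, schedules, samples_per_stage,
                             order_mode = c("curriculum", "anti", "control"),
                             seed = 1L, source_set = NULL,
                             postprocess = NULL) {
  order_mode <- match.arg(order_mode)
  if (!length(base_set)) stop_invariant("`base_set` is empty")
  if (inherits(schedules, "severity_schedule")) {
    schedules <- stats::setNames(list(schedules), schedules$artefact_type)
  }
  bs <- vapply(schedules, function(s) s$b, 0L)
  if (length(unique(bs)) != 1L) stop_invariant("all schedules must share one `b`")
  b <- bs[[1]]
  if (!is_count(samples_per_stage, 1L)) {
    stop_invariant("`samples_per_stage` must be >= 1")
  }
  if (is.null(source_set)) {
    source_set <- base_set[vapply(base_set, function(s) identical(s$label, "good"), TRUE)]
  }
  if (!length(source_set)) {
    stop_invariant("no good-quality samples available to corrupt")
  }

  n_types <- length(schedules)
  per_type <- diff(round(seq(0, samples_per_stage, length.out = n_types + 1L)))

  with_seed(seed, {
    stages <- vector("list", b)
    stage_ids <- vector("list", b)
    for (lev in seq_len(b)) {
      samples <- list(); ids <- character(0)
      for (ty in seq_len(n_types)) {
        sched <- schedules[[ty]]
        for (s in seq_len(per_type[ty])) {
          src_i <- sample.int(length(source_set), 1L)
          corr <- corrupt_at_level(source_set[[src_i]], sched, lev,
                                   seed = sample.int(.Machine$integer.max, 1L))
          if (!is.null(postprocess)) corr <- postprocess(corr, src_i)
          samples[[length(samples) + 1L]] <- corr
          ids <- c(ids, sprintf("syn_%s_l%02d_%03d", names(schedules)[ty], lev, s))
        }
      }
      stages[[lev]] <- samples
      stage_ids[[lev]] <- ids
    }

    if (order_mode == "anti") {
      stages <- rev(stages)
      stage_ids <- rev(stage_ids)
    } else if (order_mode == "control") {
      pool <- unlist(stages, recursive = FALSE)
      pool_ids <- unlist(stage_ids)
      perm <- sample.int(length(pool))
      cut <- round(seq(0, length(pool), length.out = b + 1L))
      stages <- lapply(seq_len(b), function(i) pool[perm[(cut[i] + 1L):cut[i + 1L]]])
      stage_ids <- lapply(seq_len(b), function(i) pool_ids[perm[(cut[i] + 1L):cut[i + 1L]]])
    }

    structure(list(stages = stages, stage_ids = stage_ids,
                   original_set = base_set,
                   original_ids = sprintf("orig_%03d", seq_along(base_set)),
                   b = b, order_mode = order_mode,
                   schedules = schedules, seed = seed),
              class = "curriculum")
  })
}

#' @export
print.curriculum <- function(x, ...) {
  cat(sprintf("<curriculum> %s order, b = %d stages (%s)\n", x$order_mode, x$b,
              paste(names(x$schedules), collapse = " + ")))
  cat(sprintf("  original set: %d samples; stage sizes: %s\n",
              length(x$original_set),
              paste(lengths(x$stages), collapse = ", ")))
  invisible(x)
}

#' Baby-step curriculum training
#'
#' Implements the cumulative curriculum: the training pool starts as the
#' original data set; at each stage `i` the stage's synthetic samples are
#' added (`pool = original + stages 1..i`) and the model is trained for
#' exactly `config$epochs_per_stage` epochs; after every epoch the weights
#' with the best validation balanced accuracy seen so far are retained, and
#' those best weights are returned at the end.
#'
#' With `b = 1` this is exactly one plain [train()] call on
#' `original + stage 1` with `epochs = epochs_per_stage` and early stopping
#' disabled.
#'
#' @param state A `model_state`.
#' @param curriculum A [build_curriculum()] result.
#' @param val_set Validation set from [as_training_set()]; must be disjoint
#'   from the training pool (checked via sample ids when present).
#' @param config A [train_config()]; `epochs_per_stage` is `k`.
#' @param label_levels Class labels, class 0 first.
#' @param log_batches Record minibatch ids per epoch.
#' @return A list with `state` (the model carrying the best weights) and
#'   `log` (per-stage data frame: pool size, epochs run, best validation
#'   metric and the stage/epoch of the selected checkpoint).
#' @export
curriculum_train <- function(state, curriculum, val_set,
                             config = train_config(),
                             label_levels = NULL, log_batches = FALSE) {
  if (!inherits(curriculum, "curriculum")) {
    stop_invariant("`curriculum` must be a `curriculum`")
  }
  if (!is.null(val_set$ids)) {
    overlap <- intersect(val_set$ids,
                         c(curriculum$original_ids, unlist(curriculum$stage_ids)))
    if (length(overlap)) {
      stop_invariant("validation set overlaps the training pool (e.g. %s)", overlap[1])
    }
  }

  pool <- curriculum$original_set
  pool_ids <- curriculum$original_ids
  best_metric <- -Inf
  best_weights <- model_weights(state)
  best_at <- c(stage = 0L, epoch = 0L)
  stage_log <- data.frame(stage = integer(), pool_size = integer(),
                          epochs = integer(), best_val_metric = numeric(),
                          checkpoint_stage = integer(),
                          checkpoint_epoch = integer())
  epoch_logs <- list()

  stage_cfg <- config
  stage_cfg$epochs <- config$epochs_per_stage
  stage_cfg$patience <- Inf

  for (i in seq_len(curriculum$b)) {
    pool <- c(pool, curriculum$stages[[i]])
    pool_ids <- c(pool_ids, curriculum$stage_ids[[i]])
    tset <- as_training_set(pool, label_levels = label_levels, ids = pool_ids)
    stage_cfg$seed <- config$seed + (i - 1L)
    state <- train(state, tset, val_set, stage_cfg, log_batches = log_batches)
    lg <- state$training_log
    epoch_logs[[i]] <- lg
    stage_best <- attr(lg, "best_metric")
    if (stage_best > best_metric) {
      best_metric <- stage_best
      best_weights <- model_weights(state)  # train() returns best-epoch weights
      best_at <- c(stage = i, epoch = attr(lg, "best_epoch"))
    }
    stage_log <- rbind(stage_log,
                       data.frame(stage = i, pool_size = length(pool),
                                  epochs = nrow(lg),
                                  best_val_metric = best_metric,
                                  checkpoint_stage = best_at[["stage"]],
                                  checkpoint_epoch = best_at[["epoch"]]))
  }

  state <- set_model_weights(state, best_weights)
  state$training_log <- do.call(rbind, lapply(seq_along(epoch_logs), function(i) {
    lg <- epoch_logs[[i]]
    cbind(stage = i, as.data.frame(lg))
  }))
  attr(state$training_log, "batches") <-
    if (log_batches) lapply(epoch_logs, attr, "batches") else NULL
  list(state = state, log = stage_log)
}
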