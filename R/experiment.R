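#' Configuration for an end-to-end synthetic experiment
#'
#' Bundles every stage of the pipeline (phantom generation, corruption
#' schedules, ROI extraction, model, training, curriculum, cross-validation)
#' into one structured, fully seeded configuration. The `"smoke"` preset is a
#' minutes-scale end-to-end check: 40 small sequences, a 3-stage curriculum
#' and a tiny LRCN.
#'
#' @param preset `"smoke"` or `NULL` (use the explicit arguments).
#' @param n_good,n_artefact_per_type Original data set composition.
#' @param artefact_types Artefact types to synthesise.
#' @param b Curriculum stages / severity levels.
#' @param samples_per_stage Synthetic samples per curriculum stage.
#' @param order_mode Curriculum order (`"curriculum"`, `"anti"`, `"control"`).
#' @param original_severity_levels Levels (indices into the schedule) from
#'   which the original artefact samples draw their severities.
#' @param phantom Template [phantom_config()].
#' @param crop_size ROI crop side in pixels.
#' @param radii Hough radii searched.
#' @param model A [model_spec()].
#' @param train A [train_config()].
#' @param cv_folds,cv_repeats Stratified cross-validation setup.
#' @param val_fraction Fraction of each training fold held out for validation.
#' @param seed Global seed; all stage seeds derive from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(preset = NULL,
                              n_good = 200L, n_artefact_per_type = 10L,
                              artefact_types = c("mistriggering", "breathing"),
                              b = 5L, samples_per_stage = 20L,
                              order_mode = "curriculum",
                              original_severity_levels = NULL,
                              phantom = phantom_config(),
                              crop_size = 80L, radii = 5:40,
                              model = model_spec("lrcn"),
                              train = train_config(),
                              cv_folds = 10L, cv_repeats = 1L,
                              val_fraction = 0.25, seed = 1L) {
  if (identical(preset, "smoke")) {
    phantom <- phantom_config(image_size = 48L, n_frames = 8L,
                              ventricle_radius_range = c(7, 11),
                              myocardium_thickness = 3, noise_sigma = 0.03)
    crop_size <- 32L; radii <- 4:14
    n_good <- 28L; n_artefact_per_type <- 6L
    b <- 3L; samples_per_stage <- 6L
    model <- model_spec("lrcn", input_shape = c(32L, 32L, 8L),
                        preset = "tiny", dropout_rate = 0)
    train <- train_config(batch_size = 10L, learning_rate = 0.02,
                          epochs = 6L, epochs_per_stage = 2L,
                          patience = Inf, seed = seed)
    cv_folds <- 2L; cv_repeats <- 1L
  } else if (!is.null(preset)) {
    stop_invariant("unknown preset '%s'", preset)
  }
  structure(list(n_good = n_good, n_artefact_per_type = n_artefact_per_type,
                 artefact_types = artefact_types, b = b,
                 samples_per_stage = samples_per_stage,
                 order_mode = order_mode,
                 original_severity_levels = original_severity_levels,
                 phantom = phantom, crop_size = crop_size, radii = radii,
                 model = model, train = train, cv_folds = cv_folds,
                 cv_repeats = cv_repeats, val_fraction = val_fraction,
                 seed = seed),
            class = "experiment_config")
}

default_schedules <- function(types, b) {
  stats::setNames(lapply(types, function(ty) severity_schedule(ty, b = b)), types)
}

# Generate the "original" data set, localise/crop/normalise every sequence.
prepare_dataset <- function(config) {
  schedules <- default_schedules(config$artefact_types, config$b)
  lv <- config$original_severity_levels %||% seq_len(config$b)
  specs <- lapply(config$artefact_types, function(ty) {
    lapply(lv, function(l) level_spec(schedules[[ty]], l))
  })
  names(specs) <- config$artefact_types
  raw <- generate_labelled_set(config$n_good, config$n_artefact_per_type,
                               corruption_specs = specs,
                               seed = config$seed,
                               base_config = config$phantom)
  rois <- lapply(raw, localise_roi, radii = config$radii,
                 crop_size = config$crop_size)
  prepped <- lapply(seq_along(raw), function(i) {
    normalise_intensity(crop_roi(raw[[i]], rois[[i]]))
  })
  list(raw = raw, rois = rois, sequences = prepped, schedules = schedules)
}

binary_label <- function(seqs) {
  vapply(seqs, function(s) if (identical(s$label, "good")) "good" else "artefact", "")
}

#' Run an end-to-end synthetic experiment
#'
#' Generates phantoms, corrupts a subset into artefact classes, extracts and
#' normalises ROIs, then runs stratified cross-validation: in each fold a
#' curriculum is built from the fold's training samples (fresh corruptions of
#' its good-quality members), a model is curriculum-trained and the held-out
#' fold is scored. Pooled test predictions yield the report's confusion
#' metrics, ROC curve and AUC. Everything derives from `config$seed`.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; if given, writes `metrics.json`,
#'   `roc.csv`, `training_log.csv`, `folds.csv` and `manifest.csv` there.
#' @return A report list: `metrics`, `auc`, `roc`, `scores` (per-sample
#'   pooled test scores), `folds`, `stage_logs`, `config`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (!inherits(config, "experiment_config")) {
    stop_invariant("`config` must be an `experiment_config`")
  }
  ds <- prepare_dataset(config)
  seqs <- ds$sequences
  labels <- binary_label(seqs)
  folds <- stratified_kfold(labels, k = config$cv_folds,
                            repeats = config$cv_repeats,
                            seed = config$seed + 1000L)
  n <- length(seqs)
  scores <- matrix(NA_real_, n, config$cv_repeats)
  stage_logs <- list()

  for (r in seq_len(config$cv_repeats)) {
    fr <- folds[folds$rep == r, ]
    for (f in sort(unique(fr$fold))) {
      test_idx <- fr$index[fr$fold == f]
      rest_idx <- fr$index[fr$fold != f]
      # stratified train/validation split of the remainder
      val_idx <- with_seed(config$seed + 2000L + r * 100L + f, {
        unlist(lapply(unique(labels[rest_idx]), function(cl) {
          cand <- rest_idx[labels[rest_idx] == cl]
          sample(cand, max(1L, round(length(cand) * config$val_fraction)))
        }))
      })
      train_idx <- setdiff(rest_idx, val_idx)

      # corruption happens at native image size on the raw good-quality
      # training members; synthetic samples are then cropped with their
      # source's ROI and normalised, matching the originals' preprocessing
      good_train <- train_idx[labels[train_idx] == "good"]
      curr <- build_curriculum(
        seqs[train_idx], ds$schedules,
        samples_per_stage = config$samples_per_stage,
        order_mode = config$order_mode,
        seed = config$seed + 3000L + r * 100L + f,
        source_set = ds$raw[good_train],
        postprocess = function(corr, src_i) {
          normalise_intensity(crop_roi(corr, ds$rois[[good_train[src_i]]]))
        })
      curr <- binarise_curriculum(curr)
      val_set <- as_training_set(relabel_binary(seqs[val_idx]),
                                 label_levels = c("good", "artefact"),
                                 ids = paste0("val_", val_idx))
      model <- build_model(config$model, seed = config$seed + 4000L + r * 100L + f)
      cfg <- config$train
      cfg$seed <- config$seed + 5000L + r * 100L + f
      fit <- curriculum_train(model, curr, val_set, cfg,
                              label_levels = c("good", "artefact"))
      stage_logs[[length(stage_logs) + 1L]] <-
        cbind(rep = r, fold = f, fit$log)

      test_x <- as_training_set(relabel_binary(seqs[test_idx]),
                                label_levels = c("good", "artefact"))
      probs <- predict_classes(fit$state, test_x$x)
      scores[test_idx, r] <- probs[, 2]
    }
  }

  y <- as.integer(labels == "artefact")
  pooled_scores <- rowMeans(scores)
  roc <- roc_auc(y, pooled_scores)
  cm <- confusion(y, as.integer(pooled_scores >= 0.5))
  report <- list(metrics = c(metrics(cm), auc = roc$auc),
                 auc = roc$auc, roc = roc$curve,
                 scores = data.frame(index = seq_len(n), label = labels,
                                     score = pooled_scores),
                 folds = folds,
                 stage_logs = do.call(rbind, stage_logs),
                 config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(as.list(report$metrics),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(report$roc, file.path(out_dir, "roc.csv"), row.names = FALSE)
    utils::write.csv(report$stage_logs, file.path(out_dir, "training_log.csv"),
                     row.names = FALSE)
    utils::write.csv(report$folds, file.path(out_dir, "folds.csv"),
                     row.names = FALSE)
    utils::write.csv(report$scores, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  report
}

relabel_binary <- function(seqs) {
  lapply(seqs, function(s) {
    if (!identical(s$label, "good")) s$label <- "artefact"
    s
  })
}

binarise_curriculum <- function(curr) {
  curr$stages <- lapply(curr$stages, relabel_binary)
  curr$original_set <- relabel_binary(curr$original_set)
  curr
}

#' Compare curriculum, anti-curriculum and control-curriculum training
#'
#' Runs the full baby-step comparison on a seeded imbalanced synthetic
#' benchmark. The original training set mimics a screening-population class
#' balance (many good acquisitions, few artefacts); its artefact members and
#' the held-out test artefacts draw their severities uniformly from all `b`
#' levels, emulating real artefacts whose severity is unknown. All three
#' orderings share the same originals, the same initial weights, the same
#' synthetic samples (the control permutes them) and the same held-out test
#' set, so the comparison is paired.
#'
#' @param seed Seed driving every stage of the benchmark.
#' @param order_modes Orderings to run.
#' @param n_good,n_artefact_per_type Original set composition (per artefact
#'   type; two types are used).
#' @param b Severity levels / curriculum stages.
#' @param samples_per_stage Synthetic samples added per stage.
#' @param n_test_per_class Held-out test sequences per class.
#' @param phantom Template [phantom_config()] for all generated sequences.
#' @param crop_size,radii ROI extraction parameters.
#' @param model A [model_spec()] (input shape must match `crop_size` and the
#'   phantom's frame count).
#' @param config A [train_config()]; `epochs_per_stage` is the curriculum k.
#' @return A data frame with columns `order_mode` and `auc` (held-out).
#' @export
compare_curricula <- function(seed = 1L,
                              order_modes = c("curriculum", "anti", "control"),
                              n_good = 180L, n_artefact_per_type = 10L,
                              b = 5L, samples_per_stage = 20L,
                              n_test_per_class = 40L,
                              phantom = phantom_config(
                                image_size = 48L, n_frames = 8L,
                                ventricle_radius_range = c(7, 11),
                                myocardium_thickness = 3,
                                noise_sigma = 0.08),
                              crop_size = 32L, radii = 4:14,
                              model = model_spec(
                                "lrcn", input_shape = c(32L, 32L, 8L),
                                preset = "tiny", dropout_rate = 0),
                              config = train_config(
                                batch_size = 20L, learning_rate = 0.02,
                                epochs_per_stage = 2L, seed = seed)) {
  types <- c("mistriggering", "breathing")
  schedules <- default_schedules(types, b)
  # original/test artefact severities are unknown in real data: mix all levels
  orig_specs <- stats::setNames(lapply(types, function(ty) {
    lapply(seq_len(b), function(l) level_spec(schedules[[ty]], l))
  }), types)

  prep <- function(seqs, crop) {
    lapply(seqs, function(s) {
      roi <- localise_roi(s, radii = radii, crop_size = crop)
      normalise_intensity(crop_roi(s, roi))
    })
  }

  raw_orig <- generate_labelled_set(n_good, n_artefact_per_type, orig_specs,
                                    seed = seed, base_config = phantom)
  orig <- relabel_binary(prep(raw_orig, crop_size))
  test <- relabel_binary(prep(generate_labelled_set(
    n_test_per_class, ceiling(n_test_per_class / length(types)), orig_specs,
    seed = seed + 1L, base_config = phantom), crop_size))

  labels <- vapply(orig, function(s) s$label, "")
  val_idx <- with_seed(seed + 2L, {
    unlist(lapply(unique(labels), function(cl) {
      cand <- which(labels == cl)
      sample(cand, max(1L, round(length(cand) * 0.2)))
    }))
  })
  train_idx <- setdiff(seq_along(orig), val_idx)
  good_train <- train_idx[labels[train_idx] == "good"]

  val_set <- as_training_set(orig[val_idx], c("good", "artefact"),
                             ids = paste0("val_", val_idx))
  test_set <- as_training_set(test, c("good", "artefact"))

  # pre-localise the corruption sources once; synthetic samples reuse the ROI
  rois_good <- lapply(raw_orig[good_train], localise_roi, radii = radii,
                      crop_size = crop_size)

  out <- lapply(order_modes, function(mode) {
    curr <- build_curriculum(
      orig[train_idx], schedules,
      samples_per_stage = samples_per_stage, order_mode = mode,
      seed = seed + 3L,
      source_set = raw_orig[good_train],
      postprocess = function(corr, src_i) {
        normalise_intensity(crop_roi(corr, rois_good[[src_i]]))
      })
    curr <- binarise_curriculum(curr)
    st <- build_model(model, seed = seed + 4L)
    fit <- curriculum_train(st, curr, val_set, config,
                            label_levels = c("good", "artefact"))
    probs <- predict_classes(fit$state, test_set$x)
    data.frame(order_mode = mode, auc = roc_auc(test_set$y, probs[, 2])$auc)
  })
  do.call(rbind, out)
}
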