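make_base_set <- function(n_good = 6L, n_art = 2L, seed = 1L) {
  base <- phantom_config(image_size = 40, n_frames = 4,
                         ventricle_radius_range = c(6, 9),
                         myocardium_thickness = 3, noise_sigma = 0.05)
  generate_labelled_set(n_good, n_art,
                        list(mistriggering = mistrigger_spec(z = 3)),
                        seed = seed, base_config = base)
}

test_that("curriculum stages follow the severity order; anti reverses it", {
  base <- make_base_set()
  sch <- severity_schedule("mistriggering", b = 10)
  curr <- build_curriculum(base, sch, samples_per_stage = 2,
                           order_mode = "curriculum", seed = 5)
  zs <- vapply(curr$stages, function(st) {
    st[[1]]$provenance[[length(st[[1]]$provenance)]]$z
  }, 0L)
  expect_identical(zs, seq(2L, 20L, 2L))  # increasing z = decreasing severity

  anti <- build_curriculum(base, sch, samples_per_stage = 2,
                           order_mode = "anti", seed = 5)
  anti_z <- vapply(anti$stages, function(st) {
    st[[1]]$provenance[[length(st[[1]]$provenance)]]$z
  }, 0L)
  expect_identical(anti_z, rev(zs))
  expect_identical(anti$stage_ids, rev(curr$stage_ids))
})

test_that("control curricula permute the same pooled sample multiset", {
  base <- make_base_set()
  sch <- severity_schedule("mistriggering", b = 4)
  c1 <- build_curriculum(base, sch, samples_per_stage = 3,
                         order_mode = "control", seed = 1)
  c2 <- build_curriculum(base, sch, samples_per_stage = 3,
                         order_mode = "control", seed = 2)
  expect_setequal(unlist(c1$stage_ids), unlist(c2$stage_ids))
  expect_false(identical(c1$stage_ids, c2$stage_ids))
  expect_identical(lengths(c1$stages), rep(3L, 4))
  expect_error(build_curriculum(list(), sch, 2), "empty")
})

test_that("curriculum training grows the pool cumulatively and counts epochs", {
  base <- make_base_set(n_good = 6, n_art = 2, seed = 2)
  proc <- lapply(base, function(s) {
    roi <- localise_roi(s, radii = 4:12, crop_size = 24)
    normalise_intensity(crop_roi(s, roi))
  })
  sch <- severity_schedule("mistriggering", b = 3)
  sizes <- c(2L, 2L, 2L)
  curr <- build_curriculum(proc, sch, samples_per_stage = 2,
                           order_mode = "curriculum", seed = 7)
  val <- as_training_set(relabel_val(proc[1:4]), c("good", "artefact"),
                         ids = paste0("val_", 1:4))
  spec <- model_spec("lrcn", input_shape = c(24L, 24L, 4L), preset = "tiny",
                     dropout_rate = 0)
  st <- build_model(spec, seed = 1)
  cfg <- train_config(batch_size = 8, learning_rate = 0.02,
                      epochs_per_stage = 2, seed = 9)
  curr_b <- binarise(curr)
  fit <- curriculum_train(st, curr_b, val, cfg,
                          label_levels = c("good", "artefact"),
                          log_batches = TRUE)
  n0 <- length(base)
  expect_identical(fit$log$pool_size, n0 + cumsum(sizes))
  expect_identical(fit$log$epochs, rep(2L, 3))
  expect_identical(nrow(fit$state$training_log), 6L)

  # original artefact samples appear in the sampled batches of every stage
  orig_art_ids <- curr$original_ids[vapply(base, function(s) s$label, "") != "good"]
  batches <- attr(fit$state$training_log, "batches")
  for (stage in seq_along(batches)) {
    seen <- unlist(batches[[stage]])
    expect_true(all(orig_art_ids %in% seen),
                label = sprintf("original artefacts present in stage %d", stage))
  }

  # checkpoint optimality: returned metric equals the max over all epochs
  expect_equal(max(fit$state$training_log$val_balanced_accuracy),
               fit$log$best_val_metric[3])
})

test_that("a one-stage curriculum is exactly one plain training run", {
  base <- make_base_set(n_good = 6, n_art = 2, seed = 3)
  proc <- lapply(base, function(s) {
    roi <- localise_roi(s, radii = 4:12, crop_size = 24)
    normalise_intensity(crop_roi(s, roi))
  })
  sch <- severity_schedule("mistriggering", b = 1)
  curr <- binarise(build_curriculum(proc, sch, samples_per_stage = 3, seed = 4))
  val <- as_training_set(relabel_val(proc[1:4]), c("good", "artefact"),
                         ids = paste0("val_", 1:4))
  spec <- model_spec("lrcn", input_shape = c(24L, 24L, 4L), preset = "tiny",
                     dropout_rate = 0)
  cfg <- train_config(batch_size = 8, learning_rate = 0.02,
                      epochs_per_stage = 3, seed = 13)

  fit <- curriculum_train(build_model(spec, 2), curr, val, cfg,
                          label_levels = c("good", "artefact"))

  pool <- c(curr$original_set, curr$stages[[1]])
  tset <- as_training_set(pool, c("good", "artefact"),
                          ids = c(curr$original_ids, curr$stage_ids[[1]]))
  plain_cfg <- cfg
  plain_cfg$epochs <- 3L
  plain_cfg$patience <- Inf
  plain <- train(build_model(spec, 2), tset, val, plain_cfg)

  expect_identical(fit$state$training_log$train_loss,
                   plain$training_log$train_loss)
  expect_identical(model_weights_flat(fit$state), model_weights_flat(plain))
})

test_that("validation overlap with the training pool is rejected", {
  base <- make_base_set(n_good = 4, n_art = 2, seed = 5)
  sch <- severity_schedule("mistriggering", b = 2)
  curr <- build_curriculum(base, sch, samples_per_stage = 2, seed = 6)
  val <- as_training_set(base[1:2], ids = curr$original_ids[1:2])
  spec <- model_spec("lrcn", input_shape = c(40L, 40L, 4L), preset = "tiny")
  expect_error(curriculum_train(build_model(spec, 1), curr, val,
                                train_config()),
               "overlap")
})
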