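test_that("model specs enforce the published layer structure", {
  spec <- tiny_model_spec("3dcnn")
  st <- build_model(spec, seed = 1)
  types <- vapply(st$layers, `[[`, "", "type")
  expect_identical(sum(types == "conv3"), 6L)
  expect_identical(sum(types == "pool3"), 4L)
  dense <- st$layers[types == "dense"]
  expect_length(dense, 2L)
  expect_identical(ncol(dense[[1]]$W), spec$fc_hidden)
  expect_identical(ncol(dense[[2]]$W), spec$n_classes)

  lspec <- tiny_model_spec("lrcn")
  lst <- build_model(lspec, seed = 1)
  ltypes <- vapply(lst$layers, `[[`, "", "type")
  expect_identical(sum(ltypes == "conv2"), 6L)
  expect_identical(sum(ltypes == "pool2"), 3L)
  expect_identical(sum(ltypes == "lstm"), 1L)

  expect_error(model_spec("lrcn", conv_channels = c(2, 2)), "6")
  expect_error(model_spec("lrcn", n_classes = 4), "n_classes")
})

test_that("weight initialisation is seed-deterministic", {
  spec <- tiny_model_spec("lrcn")
  a <- build_model(spec, seed = 7)
  b <- build_model(spec, seed = 7)
  c <- build_model(spec, seed = 8)
  expect_identical(model_weights_flat(a), model_weights_flat(b))
  expect_false(identical(model_weights_flat(a), model_weights_flat(c)))
})

test_that("the LRCN extractor yields one fixed-length vector per frame", {
  spec <- tiny_model_spec("lrcn", input_shape = c(16L, 16L, 4L))
  st <- build_model(spec, seed = 2)
  x <- array(runif(16 * 16 * 4 * 3), c(16, 16, 4, 3))
  fw <- cineqc:::model_forward(st, x, train = FALSE)
  flat_i <- which(vapply(st$layers, `[[`, "", "type") == "flatten")
  feat_dims <- fw$caches[[flat_i]]
  # 4 frames x 3 sequences flattened features, equal length per frame
  expect_identical(feat_dims[length(feat_dims)], 12L)
  lstm <- st$layers[[flat_i + 1L]]
  expect_equal(nrow(lstm$Wx), prod(feat_dims[-length(feat_dims)]))
})

test_that("predictions are softmax-normalised and deterministic", {
  spec <- tiny_model_spec("lrcn", input_shape = c(16L, 16L, 4L),
                          dropout_rate = 0.5)  # dropout must be off at inference
  st <- build_model(spec, seed = 3)
  x <- array(runif(16 * 16 * 4 * 5), c(16, 16, 4, 5))
  p1 <- predict(st, x)
  p2 <- predict(st, x)
  expect_identical(p1, p2)
  expect_equal(rowSums(p1), rep(1, 5), tolerance = 1e-6)
  expect_error(predict(st, array(1, c(8, 8, 4, 2))), "shape")
})

test_that("binary cross entropy matches its closed forms", {
  expect_lt(binary_cross_entropy(c(1, 0), c(1, 0)), 1e-6)
  expect_equal(binary_cross_entropy(1, 0.5), log(2), tolerance = 1e-9)
  expect_equal(binary_cross_entropy(c(1, 0), c(0.9, 0.2)),
               -(log(0.9) + log(0.8)) / 2, tolerance = 1e-12)
  # unit weights reduce exactly to the unweighted loss
  expect_identical(binary_cross_entropy(c(1, 0), c(0.9, 0.2), c(1, 1)),
                   binary_cross_entropy(c(1, 0), c(0.9, 0.2)))
  w <- c(2, 5)
  expect_equal(binary_cross_entropy(c(1, 0), c(0.9, 0.2), w),
               -(5 * log(0.9) + 2 * log(0.8)) / 2, tolerance = 1e-12)
  expect_error(binary_cross_entropy(c(1, 0), 0.5), "length")
})

test_that("analytic gradients match finite differences on both architectures", {
  for (arch in c("lrcn", "3dcnn")) {
    spec <- model_spec(arch, input_shape = c(16L, 16L, 8L), n_classes = 2L,
                       conv_channels = c(2L, 3L, 2L, 3L, 2L, 3L),
                       lstm_hidden = 4L, fc_hidden = 5L, dropout_rate = 0)
    st <- build_model(spec, seed = 3)
    set.seed(7)
    # jitter the zero-initialised biases so no pre-activation sits exactly on
    # the ReLU kink (finite differences are ill-defined there)
    for (li in seq_along(st$layers)) {
      if (!is.null(st$layers[[li]]$b)) {
        nb <- length(st$layers[[li]]$b)
        st$layers[[li]]$b <- st$layers[[li]]$b + stats::runif(nb, 0.01, 0.05)
      }
    }
    x <- array(runif(16 * 16 * 8 * 2), c(16, 16, 8, 2))
    y <- c(0L, 1L)
    fw <- cineqc:::model_forward(st, x, train = TRUE)
    ce <- cineqc:::softmax_ce(fw$logits, y, weights = c(1, 2.5))
    gr <- cineqc:::model_backward(st, fw$caches, ce$dlogits, dim(x))
    loss_at <- function(state) {
      cineqc:::softmax_ce(cineqc:::model_forward(state, x, train = TRUE)$logits,
                          y, weights = c(1, 2.5))$loss
    }
    worst <- 0; checked <- 0L
    set.seed(42)
    for (li in seq_along(st$layers)) {
      g <- gr[[li]]
      if (is.null(g)) next
      for (nm in names(g)) {
        W <- st$layers[[li]][[nm]]
        for (ii in sample(length(W), min(3, length(W)))) {
          eps <- 1e-5
          stp <- st; stp$layers[[li]][[nm]][ii] <- W[ii] + eps
          stm <- st; stm$layers[[li]][[nm]][ii] <- W[ii] - eps
          num <- (loss_at(stp) - loss_at(stm)) / (2 * eps)
          ana <- g[[nm]][ii]
          if (abs(num) > 1e-8 || abs(ana) > 1e-8) {
            checked <- checked + 1L
            worst <- max(worst, abs(num - ana) / max(abs(num) + abs(ana), 1e-8))
          }
        }
      }
    }
    expect_gt(checked, 20L)
    expect_lt(worst, 1e-5)
  }
})

test_that("one large SGD step on a single example decreases its loss", {
  spec <- tiny_model_spec("lrcn", input_shape = c(16L, 16L, 4L))
  st <- build_model(spec, seed = 5)
  set.seed(1)
  x <- array(runif(16 * 16 * 4), c(16, 16, 4, 1))
  y <- 1L
  loss_of <- function(state) {
    cineqc:::softmax_ce(cineqc:::model_forward(state, x, train = TRUE)$logits, y)$loss
  }
  l0 <- loss_of(st)
  fw <- cineqc:::model_forward(st, x, train = TRUE)
  ce <- cineqc:::softmax_ce(fw$logits, y)
  gr <- cineqc:::model_backward(st, fw$caches, ce$dlogits, dim(x))
  upd <- cineqc:::sgd_update(st, gr, cineqc:::zero_velocity(st),
                             lr = 0.5, momentum = 0)
  expect_lt(loss_of(upd$state), l0)
})

test_that("training separates clean from severely corrupted phantoms", {
  seqs <- separable_set(n_per_class = 10, seed = 21)
  labs <- vapply(seqs, function(s) s$label, "")
  tr_i <- c(which(labs == "good")[1:8], which(labs != "good")[1:8])
  va_i <- setdiff(seq_along(seqs), tr_i)
  tr <- as_training_set(seqs[tr_i])
  va <- as_training_set(seqs[va_i])
  spec <- model_spec("lrcn", input_shape = c(24L, 24L, 6L), preset = "tiny",
                     dropout_rate = 0)
  st <- build_model(spec, seed = 2)
  cfg <- train_config(batch_size = 16, learning_rate = 0.05, epochs = 150,
                      patience = Inf, seed = 3)
  st <- train(st, tr, va, cfg)
  lg <- st$training_log
  # loss trends down early and the model overfits the separable set
  expect_lt(mean(lg$train_loss[4:6]), mean(lg$train_loss[1:3]))
  expect_identical(lg$train_acc[nrow(lg)], 1)
  expect_lt(min(lg$train_loss), 0.05)
  # held-out corrupted phantom is flagged as artefact
  p <- predict(st, va$x)
  expect_gt(mean(p[va$y == 1L, 2]), 0.5)
})

test_that("training is seed-deterministic and respects the stopping contract", {
  seqs <- separable_set(n_per_class = 4, seed = 31)
  tset <- as_training_set(seqs)
  spec <- model_spec("lrcn", input_shape = c(24L, 24L, 6L), preset = "tiny",
                     dropout_rate = 0.2)
  cfg <- train_config(batch_size = 4, learning_rate = 0.05, epochs = 3,
                      patience = Inf, seed = 11)
  a <- train(build_model(spec, 1), tset, tset, cfg)
  b <- train(build_model(spec, 1), tset, tset, cfg)
  expect_identical(a$training_log$train_loss, b$training_log$train_loss)
  expect_identical(model_weights_flat(a), model_weights_flat(b))

  cfg0 <- train_config(batch_size = 4, learning_rate = 0.05, epochs = 50,
                       patience = 0, seed = 11)
  one <- train(build_model(spec, 1), tset, tset, cfg0)
  expect_identical(nrow(one$training_log), 1L)

  # single-class training set requires explicit class weights
  good_only <- as_training_set(seqs[tset$y == 0L])
  expect_error(train(build_model(spec, 1), good_only, tset, cfg),
               "single-class")
})

test_that("inverse-frequency weights reproduce the screening imbalance ratio", {
  y <- c(rep(0L, 224), rep(1L, 10))
  w <- inverse_class_weights(y)
  expect_equal(w, c(1, 22.4), tolerance = 1e-12)
  expect_error(inverse_class_weights(c(0L, 0L), n_classes = 2L), "every class")
})

test_that("translation augmentation moves content exactly and stays in range", {
  s <- tiny_phantom(seed = 2, image_size = 80, n_frames = 3)
  # forced shift moves an impulse exactly
  imp <- cine_sequence(array(0, c(80, 80, 2)))
  imp$frames[40, 40, ] <- 1
  sh <- augment_translation(imp, shift = c(3, -2))
  expect_identical(which(sh$frames[, , 1] == 1),
                   (40L + 3L) + (40L - 2L - 1L) * 80L)
  expect_identical(augment_translation(imp, shift = c(0, 0))$frames, imp$frames)

  # random shifts bounded by W/5
  set.seed(1)
  for (i in 1:20) {
    out <- augment_translation(s, max_frac = 1 / 5, seed = i)
    shift <- out$provenance[[length(out$provenance)]]$shift
    expect_true(all(abs(shift) <= 16))
  }
  expect_identical(augment_translation(s, seed = 1)$label, s$label)
})

test_that("Gaussian blur matches the sampled kernel on an impulse", {
  imp <- cine_sequence(array(0, c(33, 33, 1)))
  imp$frames[17, 17, 1] <- 1
  out <- augment_gaussian_blur(imp, sigma = 2)
  r <- ceiling(4 * 2)
  k1 <- exp(-((-r):r)^2 / (2 * 4))
  k1 <- k1 / sum(k1)
  expected <- outer(k1, k1)
  got <- out$frames[(17 - r):(17 + r), (17 - r):(17 + r), 1]
  expect_lt(max(abs(got - expected)), 1e-6)
  expect_lt(abs(sum(out$frames) - 1), 1e-6)

  # identity and constant-frame fixed points
  expect_identical(augment_gaussian_blur(imp, 0)$frames, imp$frames)
  const <- cine_sequence(array(0.4, c(20, 20, 2)))
  blurred <- augment_gaussian_blur(const, 1.5)
  inner <- blurred$frames[7:14, 7:14, ]
  expect_lt(max(abs(inner - 0.4)), 1e-9)
  expect_error(augment_gaussian_blur(const, -1), "sigma")
  relab <- augment_gaussian_blur(tiny_phantom(1, image_size = 40, n_frames = 2),
                                 1, relabel = "artefact")
  expect_identical(relab$label, "artefact")
})

test_that("three-class mode trains and predicts normalised probabilities", {
  base <- phantom_config(image_size = 40, n_frames = 4,
                         ventricle_radius_range = c(6, 9),
                         myocardium_thickness = 3, noise_sigma = 0.05)
  seqs <- generate_labelled_set(6, 3,
                                list(mistriggering = mistrigger_spec(z = 2),
                                     breathing = breathing_spec(6)),
                                seed = 61, base_config = base)
  seqs <- lapply(seqs, function(s) {
    normalise_intensity(crop_roi(s, localise_roi(s, radii = 4:12), 24))
  })
  lv <- c("good", "breathing", "mistriggering")
  tset <- as_training_set(seqs, label_levels = lv)
  spec <- model_spec("lrcn", input_shape = c(24L, 24L, 4L), n_classes = 3L,
                     conv_channels = c(2L, 2L, 2L, 2L, 2L, 2L),
                     lstm_hidden = 6L, dropout_rate = 0)
  st <- train(build_model(spec, 1), tset, tset,
              train_config(batch_size = 6, learning_rate = 0.02, epochs = 3,
                           patience = Inf, seed = 2))
  p <- predict(st, tset$x)
  expect_identical(dim(p), c(12L, 3L))
  expect_equal(rowSums(p), rep(1, 12), tolerance = 1e-6)
  ba <- evaluate_multiclass(lv[tset$y + 1L], lv[max.col(p)])
  expect_identical(sort(names(ba)), c("breathing", "mistriggering"))
})

test_that("model checkpoints round-trip through save_model/load_model", {
  spec <- tiny_model_spec("lrcn", input_shape = c(16L, 16L, 4L))
  st <- build_model(spec, seed = 9)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "model.rds")
  save_model(st, path, config = train_config())
  back <- load_model(path)
  expect_identical(model_weights_flat(back), model_weights_flat(st))
  x <- array(runif(16 * 16 * 4 * 2), c(16, 16, 4, 2))
  expect_identical(predict(st, x), predict(back, x))
  expect_error(save_model(st, path), "force")
})
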