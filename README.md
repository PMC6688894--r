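# cineqc

Motion-artefact simulation and automated quality control for 2D+time cine
cardiac MR sequences.

Cine CMR fills Cartesian k-space line by line over several heartbeats, so
ECG mistriggering and respiratory motion corrupt individual phase-encode
lines and ghost the reconstructed images. Screening cohorts contain
thousands of good acquisitions for every artefact case, which makes
supervised artefact detection a severely imbalanced problem. `cineqc` is a
toolkit for studying that problem end to end on fully synthetic data:

* **k-space corruption engine** — mistriggering (every z-th phase-encode
  line replaced by the same line of a different cardiac phase, random frame
  offset j) and breathing (per-line sub-pixel translations following a
  four-cycle sinusoid sampled at 256 phase-encode steps, applied via the
  Fourier shift theorem), both with graded severity schedules
  (`severity_schedule()`, level 1 most severe);
* **beating phantom generator** — an annular "ventricle" with known centre
  and beat frequency standing in for real acquisitions
  (`generate_phantom()`, `generate_labelled_set()`);
* **ROI localisation** — per-pixel first-harmonic temporal Fourier activity,
  circular Hough transform, kernel-based majority voting, fixed-size
  cropping and intensity normalisation (`localise_roi()`, `crop_roi()`,
  `normalise_intensity()`);
* **classifiers** — compact 3D-CNN (6 conv / 4 pool / FC-1024 / softmax) and
  LRCN (6-conv, 3-pool per-frame extractor + LSTM, prediction at the final
  step) with SGD-momentum training, early stopping on validation balanced
  accuracy, weighted cross entropy, translation and Gaussian-blur
  augmentation (`build_model()`, `train()`);
* **baby-step curriculum** — cumulative severity-ordered training stages
  with anti- and control-curriculum baselines (`build_curriculum()`,
  `curriculum_train()`, `compare_curricula()`);
* **evaluation** — confusion metrics (including the
  `(precision+recall)/2` balanced-accuracy variant used in this
  literature), ROC/AUC, repeated stratified k-fold, variance-of-Laplacian
  blur scores, 3-class one-vs-rest evaluation.

## Worked example

Corrupt a phantom, locate the ventricle, and train a tiny LRCN to tell
clean from corrupted sequences:

```r
library(cineqc)

# a 2D+time phantom and a heavily mistriggered copy
cfg  <- phantom_config(image_size = 96, n_frames = 16,
                       ventricle_radius_range = c(9, 14),
                       myocardium_thickness = 4, centre = c(40, 52))
good <- generate_phantom(cfg)
bad  <- corrupt_mistriggering(good, mistrigger_spec(z = 2, seed = 1))
mean(abs(bad$frames - good$frames))   # image-domain corruption strength
#> [1] 0.02069095

# ground-truth centre is (40, 52); the localizer recovers it from dynamics
roi <- localise_roi(good, radii = 5:20, crop_size = 48)
roi$centre
#> row col
#>  40  50

# a labelled set, cropped and normalised, then a tiny LRCN
seqs <- generate_labelled_set(40, 40,
                              list(mistriggering = mistrigger_spec(z = 2)),
                              seed = 7, base_config = cfg)
seqs <- lapply(seqs, function(s)
  normalise_intensity(crop_roi(s, localise_roi(s, radii = 5:20), 40)))
labs  <- vapply(seqs, function(s) s$label, "")
folds <- stratified_kfold(labs, k = 5, seed = 3)
tr <- as_training_set(seqs[folds$index[folds$fold > 2]])
va <- as_training_set(seqs[folds$index[folds$fold == 2]])
te <- as_training_set(seqs[folds$index[folds$fold == 1]])

spec <- model_spec("lrcn", input_shape = c(40L, 40L, 16L), preset = "tiny",
                   dropout_rate = 0)
fit <- train(build_model(spec, seed = 1), tr, va,
             train_config(batch_size = 16, learning_rate = 0.02,
                          epochs = 10, patience = Inf, seed = 2))
tail(fit$training_log[, 1:4], 3)
#>    epoch train_loss train_acc val_balanced_accuracy
#> 8      8  0.3824223 0.9791667                1.0000
#> 9      9  0.4104227 0.8541667                0.8125
#> 10    10  0.4531538 0.7708333                0.7500

roc_auc(te$y, predict(fit, te$x)[, 2])$auc   # held-out AUC
#> [1] 0.984375
```

The corruption strength (mean absolute deviation from the original) is the
quantity the severity schedules are graded on. The localizer lands within
2 px of the true centre here; the acceptance checks require 3 px on at least
95 of 100 jittered phantoms. The training log shows the loss trajectory and
the validation balanced accuracy used for checkpoint selection — the model
returned is the epoch-8 checkpoint, not the dipping final epoch — and the
held-out AUC of 0.98 reflects how separable heavy (z = 2) corruption is;
the bundled curriculum benchmark works at much subtler severities.

The severity-ordered curriculum comparison (curriculum vs anti vs control)
is one call:

```r
compare_curricula(seed = 1)   # ~2 min: 3 paired training runs
```

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/cineqc.R phantom --out seq.nii.gz --size 128 --frames 50
Rscript inst/cli/cineqc.R corrupt --type mistrigger --severity-level 1 \
    --b 10 --in seq.nii.gz --out corr.nii.gz --seed 3
Rscript inst/cli/cineqc.R roi --in corr.nii.gz --out crop.nii.gz --crop 80
Rscript inst/cli/cineqc.R run-experiment --preset smoke --out-dir results/
```

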