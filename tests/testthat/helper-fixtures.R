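# Small shared fixtures, all generated in code.

tiny_phantom_config <- function(image_size = 64L, n_frames = 12L, seed = 1L,
                                noise_sigma = 0, ...) {
  phantom_config(image_size = image_size, n_frames = n_frames,
                 ventricle_radius_range = c(8, 12), myocardium_thickness = 3,
                 noise_sigma = noise_sigma, seed = seed, ...)
}

tiny_phantom <- function(seed = 1L, ...) {
  generate_phantom(tiny_phantom_config(seed = seed, ...))
}

# A sequence of distinct constant frames: frame t has value t / 10.
constant_frame_sequence <- function(n = 8L, nt = 4L) {
  fr <- array(0, c(n, n, nt))
  for (t in seq_len(nt)) fr[, , t] <- t / 10
  cine_sequence(fr)
}

tiny_model_spec <- function(arch = "lrcn", input_shape = c(16L, 16L, 4L),
                            dropout_rate = 0, ...) {
  model_spec(arch, input_shape = as.integer(input_shape),
             conv_channels = c(2L, 2L, 2L, 2L, 2L, 2L), lstm_hidden = 6L,
             fc_hidden = 8L, dropout_rate = dropout_rate, ...)
}

# Small separable two-class set: clean phantoms vs z=2 mistriggered ones,
# cropped and normalised.
separable_set <- function(n_per_class = 8L, image_size = 40L, n_frames = 6L,
                          crop = 24L, seed = 1L) {
  base <- phantom_config(image_size = image_size, n_frames = n_frames,
                         ventricle_radius_range = c(6, 9),
                         myocardium_thickness = 3, noise_sigma = 0.05)
  seqs <- generate_labelled_set(n_per_class, n_per_class,
                                list(mistriggering = mistrigger_spec(z = 2)),
                                seed = seed, base_config = base)
  lapply(seqs, function(s) {
    roi <- localise_roi(s, radii = 4:12, crop_size = crop)
    normalise_intensity(crop_roi(s, roi))
  })
}

model_weights_flat <- function(state) {
  unlist(lapply(state$layers, function(l) {
    l[intersect(names(l), c("W", "b", "Wx", "Wh"))]
  }))
}

relabel_val <- function(seqs) {
  lapply(seqs, function(s) {
    if (!identical(s$label, "good")) s$label <- "artefact"
    s
  })
}

binarise <- function(curr) {
  curr$stages <- lapply(curr$stages, relabel_val)
  curr$original_set <- relabel_val(curr$original_set)
  curr
}
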