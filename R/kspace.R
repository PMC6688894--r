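#' Centred 2D discrete Fourier transform of one frame
#'
#' Rows are the phase-encode axis. The transform is unnormalised (DC bin of a
#' constant frame of value c is c * N^2) and centred so the zero-frequency
#' bin sits at index `floor(n/2) + 1` along each axis.
#'
#' @param frame Numeric (or complex) 2D matrix.
#' @return Complex matrix of the same size.
#' @export
to_kspace <- function(frame) {
  if (!is.matrix(frame)) {
    stop_invariant("`frame` must be a 2D matrix, got %d dims",
                   length(dim(frame)) %||% 1L)
  }
  if (!all(is.finite(Mod(frame)))) stop_invariant("`frame` contains non-finite values")
  fftshift2(stats::fft(frame))
}

#' Magnitude reconstruction from centred k-space
#'
#' Inverse of [to_kspace()] followed by taking the magnitude: corrupted
#' k-space generally inverts to a complex-valued image, and only magnitude
#' images exist downstream.
#'
#' @param k Complex 2D matrix (centred k-space).
#' @return Numeric (non-negative) matrix.
#' @export
from_kspace <- function(k) {
  if (!is.matrix(k)) stop_invariant("`k` must be a 2D matrix")
  Mod(stats::fft(ifftshift2(k), inverse = TRUE)) / length(k)
}

#' Mistriggering corruption spec
#'
#' Replaces 1 in `z` Cartesian phase-encode lines of each frame's k-space
#' with the corresponding lines of a different cardiac phase, emulating
#' ECG-trigger errors. Smaller `z` corrupts more lines and is more severe.
#'
#' @param z Positive integer stride: every z-th line is replaced.
#' @param offset_mode `"random"` (frame offset j drawn per frame) or
#'   `"fixed"` (constant `j`).
#' @param j Frame offset used when `offset_mode = "fixed"`; must satisfy
#'   1 <= j <= n_frames - 1 at application time.
#' @param line_mode `"stride"` (deterministic 1-in-z lines with a seeded
#'   random phase) or `"subset"` (a random subset of round(N/z) lines).
#' @param phase_mode `"per_frame"` (the stride phase r is redrawn for every
#'   frame, mirroring trigger jitter across the cardiac cycles that fill each
#'   frame's k-space) or `"per_sequence"` (one phase for the whole sequence).
#' @param seed RNG seed for the line phase and random offsets.
#' @return An object of class `mistrigger_spec`.
#' @export
mistrigger_spec <- function(z, offset_mode = c("random", "fixed"), j = NULL,
                            line_mode = c("stride", "subset"),
                            phase_mode = c("per_frame", "per_sequence"),
                            seed = 1L) {
  offset_mode <- match.arg(offset_mode)
  line_mode <- match.arg(line_mode)
  phase_mode <- match.arg(phase_mode)
  if (!is_count(z, min = 1L)) stop_invariant("`z` must be a positive integer")
  if (offset_mode == "fixed") {
    if (is.null(j) || !is_count(j, min = 1L)) {
      stop_invariant("fixed `offset_mode` requires an integer frame offset `j` >= 1")
    }
  }
  structure(list(z = as.integer(z), offset_mode = offset_mode,
                 j = if (is.null(j)) NULL else as.integer(j),
                 line_mode = line_mode, phase_mode = phase_mode, seed = seed),
            class = "mistrigger_spec")
}

#' Breathing corruption spec
#'
#' Emulates respiratory motion: k-space lines are taken from copies of the
#' frame translated along the phase-encode axis, with the per-line
#' displacement following a sinusoid (default: four breathing cycles sampled
#' at 256 phase-encode steps, resampled to the frame's line count).
#'
#' @param amplitude_px Peak translation in pixels (>= 0).
#' @param cycles Breathing cycles per acquisition.
#' @param n_pe_samples Sample count of the reference sinusoid.
#' @param timing `"per_frame"`: every frame sees the same within-frame
#'   sinusoid over its lines; `"global"`: one sinusoid spans the whole
#'   acquisition (frames sample successive stretches of it).
#' @param phase Optional fixed sinusoid phase in radians; by default a
#'   seeded draw from U[0, 2*pi).
#' @param seed RNG seed (for the sinusoid phase).
#' @return An object of class `breathing_spec`.
#' @export
breathing_spec <- function(amplitude_px, cycles = 4, n_pe_samples = 256L,
                           timing = c("per_frame", "global"), phase = NULL,
                           seed = 1L) {
  timing <- match.arg(timing)
  if (!is.numeric(amplitude_px) || length(amplitude_px) != 1L || amplitude_px < 0) {
    stop_invariant("`amplitude_px` must be a single number >= 0")
  }
  if (cycles <= 0) stop_invariant("`cycles` must be > 0")
  if (!is_count(n_pe_samples, min = 2L)) {
    stop_invariant("`n_pe_samples` must be an integer >= 2")
  }
  structure(list(amplitude_px = as.numeric(amplitude_px),
                 cycles = as.numeric(cycles),
                 n_pe_samples = as.integer(n_pe_samples),
                 timing = timing, phase = phase, seed = seed),
            class = "breathing_spec")
}

#' Apply mistriggering k-space corruption to a cine sequence
#'
#' For every frame i, the k-space rows with index congruent to a seeded
#' random phase r (mod z) are replaced by the same rows of frame
#' `(i + j - 1) %% n_frames + 1`; the result is reconstructed as a magnitude
#' image.
#'
#' @param seq A [cine_sequence()].
#' @param spec A [mistrigger_spec()].
#' @return A corrupted [cine_sequence()] labelled `"mistriggering"`, with z,
#'   per-frame offsets and replaced-line sets recorded in provenance.
#' @export
corrupt_mistriggering <- function(seq, spec) {
  assert_cine(seq)
  if (!inherits(spec, "mistrigger_spec")) stop_invariant("`spec` must be a `mistrigger_spec`")
  d <- dim(seq$frames)
  n_pe <- d[1]; nt <- d[3]
  if (nt < 2L) stop_invariant("mistriggering needs at least 2 frames, got %d", nt)
  if (spec$z > n_pe) {
    stop_invariant("`z` (%d) exceeds the number of phase-encode lines (%d)", spec$z, n_pe)
  }
  if (spec$offset_mode == "fixed" && spec$j > nt - 1L) {
    stop_invariant("fixed offset `j` (%d) must be <= n_frames - 1 (%d)", spec$j, nt - 1L)
  }

  with_seed(spec$seed, {
    j <- if (spec$offset_mode == "fixed") {
      rep(spec$j, nt)
    } else {
      sample.int(nt - 1L, nt, replace = TRUE)
    }
    stride_rows <- function() {
      if (spec$line_mode == "stride") {
        r <- sample.int(spec$z, 1L) - 1L          # random phase in [0, z)
        which((seq_len(n_pe) - 1L) %% spec$z == r)
      } else {
        sort(sample.int(n_pe, max(1L, round(n_pe / spec$z))))
      }
    }
    rows <- if (spec$phase_mode == "per_sequence") {
      rep(list(stride_rows()), nt)
    } else {
      lapply(seq_len(nt), function(t) stride_rows())
    }

    ks <- lapply(seq_len(nt), function(t) to_kspace(seq$frames[, , t]))
    out <- array(0, d)
    for (t in seq_len(nt)) {
      src <- (t - 1L + j[t]) %% nt + 1L
      k <- ks[[t]]
      k[rows[[t]], ] <- ks[[src]][rows[[t]], ]
      out[, , t] <- from_kspace(k)
    }
    res <- cine_sequence(out, pixel_spacing_mm = seq$pixel_spacing_mm,
                         label = "mistriggering", provenance = seq$provenance)
    add_provenance(res, list(op = "corrupt_mistriggering", z = spec$z,
                             offset_mode = spec$offset_mode, j = j,
                             rows = if (spec$phase_mode == "per_sequence")
                               rows[[1]] else rows,
                             line_mode = spec$line_mode,
                             phase_mode = spec$phase_mode,
                             seed = spec$seed))
  })
}

# Per-line displacement profile for one frame's phase-encode lines.
breathing_displacement <- function(spec, n_pe, frame_index = 1L, n_frames = 1L) {
  phase <- spec$phase
  m <- seq_len(spec$n_pe_samples) - 1L
  curve <- sin(2 * pi * spec$cycles * m / spec$n_pe_samples + phase)
  if (spec$timing == "per_frame") {
    pos <- (seq_len(n_pe) - 1L) / n_pe * spec$n_pe_samples
  } else {
    # One acquisition clock: frame t covers stretch [(t-1)/T, t/T) of the curve.
    pos <- ((frame_index - 1L) + (seq_len(n_pe) - 1L) / n_pe) / n_frames *
      spec$n_pe_samples
  }
  spec$amplitude_px *
    stats::approx(x = c(m, spec$n_pe_samples), y = c(curve, curve[1]),
                  xout = pos %% spec$n_pe_samples)$y
}

#' Apply breathing (respiratory) k-space corruption to a cine sequence
#'
#' K-space row `l` of each frame is taken from the frame translated by
#' `d(l)` pixels along the phase-encode (row) axis, where `d` is the
#' resampled sinusoidal displacement profile of the spec. Sub-pixel
#' translations use the Fourier shift theorem; translation is circular.
#' A positive displacement moves image content towards larger row indices.
#'
#' @param seq A [cine_sequence()].
#' @param spec A [breathing_spec()].
#' @return A corrupted [cine_sequence()] labelled `"breathing"`.
#' @export
corrupt_breathing <- function(seq, spec) {
  assert_cine(seq)
  if (!inherits(spec, "breathing_spec")) stop_invariant("`spec` must be a `breathing_spec`")
  d <- dim(seq$frames)
  n_pe <- d[1]; nt <- d[3]

  spec_run <- spec
  if (is.null(spec_run$phase)) {
    spec_run$phase <- with_seed(spec$seed, stats::runif(1, 0, 2 * pi))
  }

  freqs <- centred_freqs(n_pe)
  out <- array(0, d)
  for (t in seq_len(nt)) {
    disp <- breathing_displacement(spec_run, n_pe, frame_index = t, n_frames = nt)
    k <- to_kspace(seq$frames[, , t])
    # Row l of the corrupted k-space equals row l of the k-space of the
    # image shifted by disp[l]: multiply by the shift-theorem phase ramp.
    k <- k * exp(-2i * pi * freqs * disp / n_pe)
    out[, , t] <- from_kspace(k)
  }
  res <- cine_sequence(out, pixel_spacing_mm = seq$pixel_spacing_mm,
                       label = "breathing", provenance = seq$provenance)
  add_provenance(res, list(op = "corrupt_breathing",
                           amplitude_px = spec$amplitude_px,
                           cycles = spec$cycles,
                           n_pe_samples = spec$n_pe_samples,
                           timing = spec$timing, phase = spec_run$phase,
                           seed = spec$seed))
}

#' Graded severity schedule for synthetic artefacts
#'
#' Level 1 is the most severe (easiest to classify), level `b` the least
#' severe. Mistriggering severity is controlled by the line-replacement
#' stride z (default z = 2, 4, ..., 2b, so the corrupted-line fraction falls
#' from 1/2 to 1/(2b)); breathing severity by the translation amplitude
#' (default log-spaced from 8 px down to 0.8 px). The default strides share
#' one parity: for a real-valued image, k-space rows pair up by conjugate
#' symmetry, and the chance that a stride pattern replaces both members of a
#' pair depends on the parity of z, so mixing parities would make
#' image-domain severity non-monotone across levels.
#'
#' @param artefact_type `"mistriggering"` or `"breathing"`.
#' @param b Number of severity levels (>= 1).
#' @param z_values Optional explicit strictly increasing z values (mistriggering).
#' @param amplitude_range Optional (max, min) amplitudes in px (breathing).
#' @return An object of class `severity_schedule` with a `levels` data frame.
#' @export
severity_schedule <- function(artefact_type = c("mistriggering", "breathing"),
                              b = 10L, z_values = NULL,
                              amplitude_range = c(8, 0.8)) {
  artefact_type <- match.arg(artefact_type)
  if (!is_count(b, min = 1L)) stop_invariant("`b` must be an integer >= 1")
  b <- as.integer(b)
  if (artefact_type == "mistriggering") {
    z <- if (is.null(z_values)) seq(2L, 2L * b, by = 2L) else as.integer(z_values)
    if (length(z) != b || is.unsorted(z, strictly = TRUE)) {
      stop_invariant("`z_values` must be %d strictly increasing integers", b)
    }
    levels <- data.frame(level = seq_len(b), z = z)
  } else {
    a <- if (b == 1L) {
      amplitude_range[1]
    } else {
      exp(seq(log(amplitude_range[1]), log(amplitude_range[2]), length.out = b))
    }
    if (is.unsorted(rev(a), strictly = TRUE)) {
      stop_invariant("breathing amplitudes must be strictly decreasing")
    }
    levels <- data.frame(level = seq_len(b), amplitude_px = a)
  }
  structure(list(artefact_type = artefact_type, b = b, levels = levels),
            class = "severity_schedule")
}

#' Corruption spec for one level of a severity schedule
#'
#' @param schedule A [severity_schedule()].
#' @param level Level index in 1..b (1 = most severe).
#' @param seed RNG seed for the resulting spec.
#' @return A [mistrigger_spec()] or [breathing_spec()].
#' @export
level_spec <- function(schedule, level, seed = 1L) {
  if (!inherits(schedule, "severity_schedule")) {
    stop_invariant("`schedule` must be a `severity_schedule`")
  }
  if (!is_count(level, min = 1L) || level > schedule$b) {
    stop_invariant("`level` must be in 1..%d", schedule$b)
  }
  if (schedule$artefact_type == "mistriggering") {
    mistrigger_spec(z = schedule$levels$z[level], seed = seed)
  } else {
    breathing_spec(amplitude_px = schedule$levels$amplitude_px[level], seed = seed)
  }
}

#' Corrupt a sequence at a given severity level
#'
#' @inheritParams level_spec
#' @param seq A [cine_sequence()].
#' @return The corrupted sequence.
#' @export
corrupt_at_level <- function(seq, schedule, level, seed = 1L) {
  apply_corruption(seq, level_spec(schedule, level, seed = seed))
}
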