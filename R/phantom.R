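#' Configuration for the beating-annulus cine phantom
#'
#' The phantom emulates a short-axis bSSFP cine slice: a bright myocardial
#' ring (the "ventricle") on a darker blood pool and background, contracting
#' and dilating sinusoidally over the cardiac cycle. It provides known ground
#' truth (centre, beat frequency) for testing localisation and classification
#' without access to real acquisitions.
#'
#' @param image_size Pixels per side of the square frame.
#' @param n_frames Number of time frames (a cine acquisition typically has 50).
#' @param centre Numeric (row, col), 1-based pixel coordinates of the annulus
#'   centre. Defaults to the image centre.
#' @param ventricle_radius_range Numeric (min, max): the inner (endocardial)
#'   radius oscillates between these values over the beat.
#' @param myocardium_thickness Ring thickness in pixels.
#' @param beat_cycles Number of full contraction cycles across the sequence.
#' @param noise_sigma Standard deviation of additive Gaussian noise
#'   (clipped at zero), in intensity units.
#' @param intensities Named numeric with `background`, `blood`, `myocardium`
#'   intensity levels, mimicking bSSFP contrast.
#' @param pixel_spacing_mm In-plane pixel spacing, mm.
#' @param seed RNG seed for the noise.
#'
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 128L, n_frames = 50L, centre = NULL,
                           ventricle_radius_range = c(12, 20),
                           myocardium_thickness = 5,
                           beat_cycles = 1, noise_sigma = 0,
                           intensities = c(background = 0.1, blood = 0.5,
                                           myocardium = 0.9),
                           pixel_spacing_mm = c(1.8, 1.8), seed = 1L) {
  if (is.null(centre)) centre <- rep((image_size + 1) / 2, 2L)
  cfg <- structure(
    list(image_size = as.integer(image_size), n_frames = as.integer(n_frames),
         centre = as.numeric(centre),
         ventricle_radius_range = as.numeric(ventricle_radius_range),
         myocardium_thickness = as.numeric(myocardium_thickness),
         beat_cycles = as.numeric(beat_cycles),
         noise_sigma = as.numeric(noise_sigma),
         intensities = intensities,
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         seed = seed),
    class = "phantom_config"
  )
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  r <- cfg$ventricle_radius_range
  if (!(r[1] > 0 && r[1] < r[2] && r[2] < cfg$image_size / 2)) {
    stop_invariant(
      "invalid `ventricle_radius_range`: need 0 < min (%g) < max (%g) < image_size/2 (%g)",
      r[1], r[2], cfg$image_size / 2)
  }
  margin <- r[2] + cfg$myocardium_thickness
  if (any(cfg$centre < 1 + margin) || any(cfg$centre > cfg$image_size - margin)) {
    stop_invariant(
      "invalid `centre`: (%g, %g) is closer than radius_max + thickness (%g px) to a border",
      cfg$centre[1], cfg$centre[2], margin)
  }
  if (cfg$n_frames < 2L) {
    stop_invariant("invalid `n_frames`: need at least 2 frames, got %d", cfg$n_frames)
  }
  if (cfg$noise_sigma < 0) stop_invariant("invalid `noise_sigma`: must be >= 0")
  invisible(cfg)
}

# Linear 1-px-wide soft edge: 0 below the boundary, 1 above.
soft_step <- function(x) clamp(x + 0.5, 0, 1)

#' Generate a beating-annulus cine phantom
#'
#' The endocardial radius follows half a cosine range over each beat so that
#' an integer number of `beat_cycles` closes periodically: frame 1 and frame
#' `n_frames` are identical in the noise-free case.
#'
#' @param config A [phantom_config()].
#' @return A [cine_sequence()] labelled `"good"`.
#' @export
#' @examples
#' seq <- generate_phantom(phantom_config(image_size = 64, n_frames = 10,
#'                                        ventricle_radius_range = c(6, 10),
#'                                        myocardium_thickness = 3))
#' dim(seq)
generate_phantom <- function(config) {
  if (!inherits(config, "phantom_config")) {
    stop_invariant("`config` must be a `phantom_config`")
  }
  validate_phantom_config(config)
  n <- config$image_size
  t_idx <- seq_len(config$n_frames)
  # Phase runs through beat_cycles full periods from first to last frame.
  phase <- 2 * pi * config$beat_cycles * (t_idx - 1) / (config$n_frames - 1)
  r <- config$ventricle_radius_range
  r_mid <- mean(r); r_amp <- diff(r) / 2
  r_in <- r_mid - r_amp * cos(phase)

  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  d <- sqrt((rows - config$centre[1])^2 + (cols - config$centre[2])^2)

  lev <- config$intensities
  frames <- array(0, c(n, n, config$n_frames))
  for (t in t_idx) {
    outer_m <- soft_step(r_in[t] + config$myocardium_thickness - d)
    inner_m <- soft_step(r_in[t] - d)
    frames[, , t] <- lev[["background"]] +
      (lev[["myocardium"]] - lev[["background"]]) * outer_m -
      (lev[["myocardium"]] - lev[["blood"]]) * inner_m
  }
  if (config$noise_sigma > 0) {
    frames <- with_seed(config$seed, {
      pmax(frames + array(stats::rnorm(length(frames), 0, config$noise_sigma),
                          dim(frames)), 0)
    })
  }
  cine_sequence(frames, pixel_spacing_mm = config$pixel_spacing_mm,
                label = "good",
                provenance = list(list(op = "generate_phantom",
                                       centre = config$centre,
                                       radius_range = r,
                                       beat_cycles = config$beat_cycles,
                                       noise_sigma = config$noise_sigma,
                                       seed = config$seed)))
}

#' Generate a labelled set of phantoms with optional synthetic artefacts
#'
#' Produces `n_good` clean phantoms plus `n_artefact_per_type` corrupted
#' phantoms per artefact type, with randomised centres and radii (so that ROI
#' localisation is not trivially solvable). Artefact members are created by
#' corrupting a fresh clean phantom with the supplied corruption spec;
#' when a list of specs is given for a type, one is drawn at random per
#' sample (e.g. to mix severities).
#'
#' @param n_good Number of good-quality sequences.
#' @param n_artefact_per_type Number of corrupted sequences per artefact type.
#' @param corruption_specs Named list: names are artefact types
#'   (`"mistriggering"`, `"breathing"`), values a corruption spec
#'   ([mistrigger_spec()] / [breathing_spec()]) or a list of such specs.
#' @param seed RNG seed controlling geometry jitter and corruption seeds.
#' @param base_config Template [phantom_config()]; centre and radii are
#'   re-drawn per sample within the valid region.
#'
#' @return A list of [cine_sequence()] objects with labels set.
#' @export
generate_labelled_set <- function(n_good, n_artefact_per_type = 0L,
                                  corruption_specs = list(), seed = 1L,
                                  base_config = phantom_config()) {
  if (!is_count(n_good) || !is_count(n_artefact_per_type)) {
    stop_invariant("`n_good` and `n_artefact_per_type` must be non-negative integers")
  }
  types <- names(corruption_specs)
  n_total <- n_good + n_artefact_per_type * length(types)
  if (n_total == 0L) stop_invariant("requested an empty set (zero total size)")
  if (n_artefact_per_type > 0L && length(types) == 0L) {
    stop_invariant("artefact sequences requested but `corruption_specs` is empty")
  }

  labels <- c(rep("good", n_good),
              rep(types, each = n_artefact_per_type))
  with_seed(seed, {
    out <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      cfg <- jitter_phantom_config(base_config,
                                   seed = sample.int(.Machine$integer.max, 1L))
      s <- generate_phantom(cfg)
      if (labels[i] != "good") {
        spec <- corruption_specs[[labels[i]]]
        if (is.list(spec) && !inherits(spec, c("mistrigger_spec", "breathing_spec"))) {
          spec <- spec[[sample.int(length(spec), 1L)]]
        }
        spec$seed <- sample.int(.Machine$integer.max, 1L)
        s <- apply_corruption(s, spec)
      }
      out[[i]] <- s
    }
    out
  })
}

#' Randomise a phantom configuration's geometry
#'
#' Redraws the annulus centre and radii uniformly within the
#' valid-configuration region (so localisation cannot rely on a fixed
#' centre), keeping all other settings.
#'
#' @param cfg A [phantom_config()] template.
#' @param seed Seed stored in the returned config (the geometry draw uses the
#'   current RNG stream).
#' @return A valid [phantom_config()] with jittered `centre` and
#'   `ventricle_radius_range`.
#' @export
jitter_phantom_config <- function(cfg, seed) {
  r <- cfg$ventricle_radius_range
  span <- diff(r)
  r_min <- stats::runif(1, max(2, r[1] - span / 2), r[1] + span / 2)
  r_max <- r_min + span
  margin <- r_max + cfg$myocardium_thickness + 1
  lo <- 1 + margin; hi <- cfg$image_size - margin
  if (hi <= lo) stop_invariant("image too small for the requested annulus jitter")
  centre <- stats::runif(2, lo, hi)
  cfg$centre <- centre
  cfg$ventricle_radius_range <- c(r_min, r_max)
  cfg$seed <- seed
  validate_phantom_config(cfg)
  cfg
}

apply_corruption <- function(seq, spec) {
  if (inherits(spec, "mistrigger_spec")) {
    corrupt_mistriggering(seq, spec)
  } else if (inherits(spec, "breathing_spec")) {
    corrupt_breathing(seq, spec)
  } else {
    stop_invariant("unknown corruption spec of class <%s>", class(spec)[1])
  }
}
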