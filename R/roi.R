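#' Temporal activity image at the heart-beat frequency
#'
#' Each slice sequence captures one heartbeat, so the beat frequency is the
#' first temporal Fourier bin. The activity image is, per pixel, the
#' magnitude of that first-harmonic coefficient (unnormalised DFT; the DC
#' component is excluded by construction). A pixel varying as
#' `a * cos(2*pi*t/T)` has activity `a*T/2`.
#'
#' @param seq A [cine_sequence()] with at least 2 frames.
#' @param harmonic Temporal frequency bin to use (default 1, one beat per
#'   sequence; configurable for multi-beat data).
#' @return An object of class `activity_image` with fields `values`
#'   (non-negative matrix) and `beat_frequency_index`.
#' @export
temporal_activity <- function(seq, harmonic = 1L) {
  assert_cine(seq)
  d <- dim(seq$frames)
  nt <- d[3]
  if (nt < 2L) stop_invariant("temporal activity needs at least 2 frames")
  if (!is_count(harmonic, min = 1L) || harmonic >= nt) {
    stop_invariant("`harmonic` must be an integer in 1..%d", nt - 1L)
  }
  m <- matrix(seq$frames, d[1] * d[2], nt)
  basis <- exp(-2i * pi * harmonic * (seq_len(nt) - 1L) / nt)
  act <- matrix(Mod(m %*% basis), d[1], d[2])
  if (max(act) < 1e-12) {
    warning("sequence is constant in time: activity image is all zero",
            call. = FALSE)
    act[] <- 0
  }
  structure(list(values = act, beat_frequency_index = as.integer(harmonic)),
            class = "activity_image")
}

# Gradient-magnitude edge map, thresholded at a percentile of the
# non-zero gradient values.
edge_map <- function(values, percentile = 0.9) {
  h <- nrow(values); w <- ncol(values)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gy[2:(h - 1), ] <- (values[3:h, ] - values[1:(h - 2), ]) / 2
  gx[, 2:(w - 1)] <- (values[, 3:w] - values[, 1:(w - 2)]) / 2
  gm <- sqrt(gx^2 + gy^2)
  pos <- gm[gm > 0]
  if (!length(pos)) return(matrix(FALSE, h, w))
  gm >= stats::quantile(pos, percentile)
}

# Unique integer perimeter offsets of a circle of the given radius.
circle_offsets <- function(radius) {
  n <- max(8L, ceiling(2 * pi * radius))
  th <- 2 * pi * (seq_len(n) - 1L) / n
  unique(data.frame(dr = round(radius * cos(th)), dc = round(radius * sin(th))))
}

#' Hough circle candidates from an activity image
#'
#' Builds an edge map from the activity image, accumulates circular Hough
#' votes over the radius range, keeps the best circle per radius and returns
#' the top `n_keep` overall, sorted by score (vote fraction of the perimeter)
#' descending. Ties are broken by smaller radius, then by first centre in
#' column-major order.
#'
#' @param activity An `activity_image` from [temporal_activity()].
#' @param radii Integer vector of radii (pixels) to search.
#' @param n_keep Number of candidates to retain (default 10).
#' @param edge_percentile Gradient-magnitude percentile defining edges.
#' @return A list of `circle_candidate` objects (fields `centre`, `radius`,
#'   `score`).
#' @export
hough_candidates <- function(activity, radii = 5:40, n_keep = 10L,
                             edge_percentile = 0.9) {
  if (!inherits(activity, "activity_image")) {
    stop_invariant("`activity` must be an `activity_image`")
  }
  v <- activity$values
  if (max(v) <= 0) stop_invariant("all-zero activity image: cannot localise")
  h <- nrow(v); w <- ncol(v)
  edges <- which(edge_map(v, edge_percentile), arr.ind = TRUE)
  if (nrow(edges) == 0L) stop_invariant("no edges found in the activity image")

  cands <- vector("list", length(radii))
  for (i in seq_along(radii)) {
    off <- circle_offsets(radii[i])
    acc <- numeric(h * w)
    for (o in seq_len(nrow(off))) {
      rr <- edges[, 1] - off$dr[o]
      cc <- edges[, 2] - off$dc[o]
      ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
      if (any(ok)) {
        idx <- rr[ok] + (cc[ok] - 1L) * h
        tab <- tabulate(idx, nbins = h * w)
        acc <- acc + tab
      }
    }
    best <- which.max(acc)  # first maximum in column-major order
    cands[[i]] <- list(centre = c(row = (best - 1L) %% h + 1L,
                                  col = (best - 1L) %/% h + 1L),
                       radius = radii[i],
                       score = acc[best] / nrow(off))
  }
  ord <- order(-vapply(cands, `[[`, 0, "score"),
               vapply(cands, `[[`, 0, "radius"))
  cands <- cands[ord][seq_len(min(n_keep, length(cands)))]
  lapply(cands, function(x) structure(x, class = "circle_candidate"))
}

#' Kernel-based majority vote over circle candidates
#'
#' Each candidate centre contributes an isotropic Gaussian kernel scaled by
#' its score; the kernels are summed into a likelihood surface whose argmax
#' is the ROI centre. Accepts the candidates of a single slice or a list of
#' candidate sets from several slices.
#'
#' @param candidate_sets A list of `circle_candidate`s, or a list of such
#'   lists (one per slice).
#' @param image_dim Integer (height, width) of the source frames.
#' @param kernel_sigma Gaussian kernel width in pixels.
#' @param crop_size Side of the ROI crop recorded in the result.
#' @return An object of class `roi_result` with fields `centre`,
#'   `likelihood_surface`, `crop_size`.
#' @export
vote_centre <- function(candidate_sets, image_dim, kernel_sigma = 5,
                        crop_size = 80L) {
  if (inherits(candidate_sets, "circle_candidate")) {
    candidate_sets <- list(candidate_sets)
  }
  if (length(candidate_sets) && inherits(candidate_sets[[1]], "circle_candidate")) {
    candidate_sets <- list(candidate_sets)
  }
  cands <- unlist(candidate_sets, recursive = FALSE)
  if (!length(cands)) stop_invariant("no circle candidates to vote over")
  h <- image_dim[1]; w <- image_dim[2]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  surface <- matrix(0, h, w)
  for (cd in cands) {
    surface <- surface + cd$score *
      exp(-((rows - cd$centre[1])^2 + (cols - cd$centre[2])^2) /
            (2 * kernel_sigma^2))
  }
  best <- which.max(surface)
  centre <- c(row = (best - 1L) %% h + 1L, col = (best - 1L) %/% h + 1L)
  structure(list(centre = centre, likelihood_surface = surface,
                 crop_size = as.integer(crop_size)),
            class = "roi_result")
}

#' Locate the ventricle centre of one or more slice sequences
#'
#' Convenience wrapper: temporal activity, Hough candidates and kernel
#' voting in one call.
#'
#' @param seqs A [cine_sequence()] or list of them (slices of one subject).
#' @inheritParams hough_candidates
#' @inheritParams vote_centre
#' @return An `roi_result`.
#' @export
localise_roi <- function(seqs, radii = 5:40, n_keep = 10L,
                         edge_percentile = 0.9, kernel_sigma = 5,
                         crop_size = 80L) {
  if (inherits(seqs, "cine_sequence")) seqs <- list(seqs)
  sets <- lapply(seqs, function(s) {
    hough_candidates(temporal_activity(s), radii = radii, n_keep = n_keep,
                     edge_percentile = edge_percentile)
  })
  vote_centre(sets, image_dim = dim(seqs[[1]]$frames)[1:2],
              kernel_sigma = kernel_sigma, crop_size = crop_size)
}

#' Crop a fixed-size ROI around a located centre
#'
#' The `crop_size` x `crop_size` window is centred on `roi$centre` and
#' clamped to the image bounds (so the output size is always exact).
#'
#' @param seq A [cine_sequence()].
#' @param roi An `roi_result` (or a length-2 numeric centre).
#' @param crop_size Window side in pixels; defaults to `roi$crop_size`.
#' @return The cropped [cine_sequence()]; provenance records the offset.
#' @export
crop_roi <- function(seq, roi, crop_size = NULL) {
  assert_cine(seq)
  centre <- if (inherits(roi, "roi_result")) roi$centre else roi
  crop <- as.integer(crop_size %||%
                       (if (inherits(roi, "roi_result")) roi$crop_size else 80L))
  d <- dim(seq$frames)
  if (crop > d[1] || crop > d[2]) {
    stop_invariant("`crop_size` (%d) exceeds image size (%d x %d)", crop, d[1], d[2])
  }
  r0 <- clamp(round(centre[1]) - crop %/% 2, 1L, d[1] - crop + 1L)
  c0 <- clamp(round(centre[2]) - crop %/% 2, 1L, d[2] - crop + 1L)
  out <- seq$frames[r0:(r0 + crop - 1L), c0:(c0 + crop - 1L), , drop = FALSE]
  res <- seq
  res$frames <- out
  add_provenance(res, list(op = "crop_roi", offset = c(r0, c0), crop_size = crop))
}

#' Standardise sequence intensities
#'
#' Rescales a sequence to zero mean and unit (population) standard deviation,
#' computed over the whole 2D+time volume. Affine-invariant: `a*x + b`
#' (a > 0) normalises to the same output as `x`.
#'
#' @param seq A [cine_sequence()] with non-constant intensities.
#' @return The normalised [cine_sequence()] (`normalised = TRUE`).
#' @export
normalise_intensity <- function(seq) {
  assert_cine(seq)
  x <- seq$frames
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s < 1e-12) stop_invariant("cannot normalise a constant-intensity sequence")
  res <- seq
  res$frames <- (x - m) / s
  res$normalised <- TRUE
  add_provenance(res, list(op = "normalise_intensity", mean = m, sd = s))
}
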