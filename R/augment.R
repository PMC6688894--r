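#' Random translation augmentation
#'
#' Shifts the whole sequence by an integer offset drawn uniformly in
#' `[-floor(W*max_frac), floor(W*max_frac)]` per axis (the classic
#' width/5-style jitter), filling exposed pixels with zero. The label is
#' preserved.
#'
#' @param seq A [cine_sequence()].
#' @param max_frac Maximum shift as a fraction of the image side.
#' @param seed RNG seed (ignored when `shift` is given).
#' @param shift Optional fixed integer (row, col) shift, for reproducible
#'   augmentation.
#' @return The translated [cine_sequence()].
#' @export
augment_translation <- function(seq, max_frac = 1 / 5, seed = NULL,
                                shift = NULL) {
  assert_cine(seq)
  if (max_frac <= 0 || max_frac >= 1) stop_invariant("`max_frac` must be in (0, 1)")
  d <- dim(seq$frames)
  if (is.null(shift)) {
    mr <- floor(d[1] * max_frac); mc <- floor(d[2] * max_frac)
    shift <- with_seed(seed, c(sample(-mr:mr, 1L), sample(-mc:mc, 1L)))
  }
  shift <- as.integer(shift)
  out <- array(0, d)
  src_r <- seq_len(d[1]) - shift[1]
  src_c <- seq_len(d[2]) - shift[2]
  ok_r <- src_r >= 1L & src_r <= d[1]
  ok_c <- src_c >= 1L & src_c <= d[2]
  out[which(ok_r), which(ok_c), ] <- seq$frames[src_r[ok_r], src_c[ok_c], ,
                                                drop = FALSE]
  res <- seq
  res$frames <- out
  add_provenance(res, list(op = "augment_translation", shift = shift))
}

gaussian_kernel_1d <- function(sigma) {
  r <- ceiling(4 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Zero-padded separable convolution of one frame.
blur_frame <- function(frame, kern) {
  r <- (length(kern) - 1L) / 2L
  h <- nrow(frame); w <- ncol(frame)
  pad <- matrix(0, h + 2L * r, w)
  pad[r + seq_len(h), ] <- frame
  tmp <- matrix(0, h, w)
  for (i in seq_along(kern)) tmp <- tmp + kern[i] * pad[(i - 1L) + seq_len(h), ]
  pad2 <- matrix(0, h, w + 2L * r)
  pad2[, r + seq_len(w)] <- tmp
  out <- matrix(0, h, w)
  for (i in seq_along(kern)) out <- out + kern[i] * pad2[, (i - 1L) + seq_len(w)]
  out
}

#' Gaussian blurring augmentation
#'
#' Spatially blurs every frame with an isotropic Gaussian (separable
#' convolution, kernel truncated at 4 sigma, zero padding). `sigma = 0` is
#' the identity. Blurred copies used to balance classes carry the artefact
#' label via `relabel`.
#'
#' @param seq A [cine_sequence()].
#' @param sigma Blur standard deviation in pixels (>= 0).
#' @param relabel Optional new label for the blurred copy.
#' @return The blurred [cine_sequence()].
#' @export
augment_gaussian_blur <- function(seq, sigma, relabel = NULL) {
  assert_cine(seq)
  if (sigma < 0) stop_invariant("`sigma` must be >= 0")
  res <- seq
  if (sigma > 0) {
    kern <- gaussian_kernel_1d(sigma)
    d <- dim(seq$frames)
    out <- array(0, d)
    for (t in seq_len(d[3])) out[, , t] <- blur_frame(seq$frames[, , t], kern)
    res$frames <- out
  }
  if (!is.null(relabel)) res$label <- relabel
  add_provenance(res, list(op = "augment_gaussian_blur", sigma = sigma))
}
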