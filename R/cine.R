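#' Cine sequence container
#'
#' A `cine_sequence` holds one 2D+time magnitude slice sequence as a numeric
#' array of dimension height x width x n_frames, together with its in-plane
#' pixel spacing, an optional quality label and a free-form provenance record
#' of the operations (corruptions, crops, augmentations) applied to it.
#'
#' @param frames Numeric 3D array, height x width x n_frames. All values must
#'   be finite; raw magnitude sequences are non-negative (intensity
#'   normalisation produces signed values and sets `normalised = TRUE`).
#' @param pixel_spacing_mm Length-2 numeric, (row, col) spacing in mm.
#' @param label Optional quality label, e.g. `"good"`, `"mistriggering"`,
#'   `"breathing"` or `"artefact"`.
#' @param provenance A list of records describing how the sequence was made.
#' @param normalised Logical; `TRUE` once intensities have been standardised
#'   (negative values are then permitted).
#'
#' @return An object of class `cine_sequence`.
#' @export
cine_sequence <- function(frames, pixel_spacing_mm = c(1.8, 1.8),
                          label = NA_character_, provenance = list(),
                          normalised = FALSE) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop_invariant("`frames` must be a 3D array (height x width x n_frames), got %s dims",
                   length(dim(frames)))
  }
  if (!all(is.finite(frames))) {
    stop_invariant("`frames` contains non-finite intensities")
  }
  if (!normalised && any(frames < 0)) {
    stop_invariant("`frames` contains negative intensities in a non-normalised sequence")
  }
  if (length(pixel_spacing_mm) != 2L || any(pixel_spacing_mm <= 0)) {
    stop_invariant("`pixel_spacing_mm` must be two positive numbers")
  }
  structure(
    list(frames = frames,
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         label = label,
         provenance = provenance,
         normalised = isTRUE(normalised)),
    class = "cine_sequence"
  )
}

#' @export
print.cine_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cine_sequence> %d x %d pixels, %d frames (%.2g x %.2g mm)\n",
              d[1], d[2], d[3], x$pixel_spacing_mm[1], x$pixel_spacing_mm[2]))
  cat(sprintf("  label: %s%s\n", x$label,
              if (x$normalised) " [intensity-normalised]" else ""))
  if (length(x$provenance)) {
    cat(sprintf("  provenance: %s\n",
                paste(vapply(x$provenance, function(p) p$op %||% "?", ""),
                      collapse = " -> ")))
  }
  invisible(x)
}

#' @export
dim.cine_sequence <- function(x) dim(x$frames)

n_frames <- function(seq) dim(seq$frames)[3L]

assert_cine <- function(seq) {
  if (!inherits(seq, "cine_sequence")) {
    stop_invariant("expected a `cine_sequence`, got <%s>", class(seq)[1])
  }
  invisible(seq)
}

add_provenance <- function(seq, record) {
  seq$provenance <- c(seq$provenance, list(record))
  seq
}
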