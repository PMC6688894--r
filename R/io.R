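#' Read a cine sequence from a NIfTI file
#'
#' Axes are interpreted as (row, col, time); pixel spacing is taken from the
#' header. A provenance JSON sidecar (`<path>.json`), if present, restores
#' the label and corruption record.
#'
#' @param path Path to a 3D NIfTI file.
#' @return A [cine_sequence()].
#' @export
read_cine <- function(path) {
  if (!file.exists(path)) stop_invariant("file not found: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_invariant("cannot read '%s': %s",
                                                     path, conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 3L) {
    stop_invariant("'%s' has %d dimensions; expected a 3D (row, col, time) volume",
                   path, length(d))
  }
  spacing <- RNifti::pixdim(img)[1:2]
  label <- NA_character_; provenance <- list(); normalised <- FALSE
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
    label <- meta$label %||% NA_character_
    provenance <- meta$provenance %||% list()
    normalised <- isTRUE(meta$normalised)
  }
  cine_sequence(array(as.numeric(img), d), pixel_spacing_mm = spacing,
                label = label, provenance = provenance,
                normalised = normalised)
}

#' Write a cine sequence to a NIfTI file
#'
#' Writes the (row, col, time) volume with the pixel spacing in the header
#' and a JSON sidecar (`<path>.json`) recording label and provenance.
#' Refuses to overwrite an existing file unless `force = TRUE`.
#'
#' @param seq A [cine_sequence()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param force Overwrite an existing file.
#' @param sidecar Write the provenance sidecar.
#' @return `path`, invisibly.
#' @export
write_cine <- function(seq, path, force = FALSE, sidecar = TRUE) {
  assert_cine(seq)
  if (file.exists(path) && !force) {
    stop_invariant("'%s' exists; use `force = TRUE` to overwrite", path)
  }
  img <- RNifti::asNifti(seq$frames)
  RNifti::pixdim(img) <- c(seq$pixel_spacing_mm, 1)
  RNifti::writeNifti(img, path)
  if (sidecar) {
    jsonlite::write_json(list(label = seq$label,
                              normalised = seq$normalised,
                              provenance = seq$provenance),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Write a dataset manifest
#'
#' One row per sequence: file, label, seed, corruption type and severity
#' parameter, extracted from each sequence's provenance.
#'
#' @param seqs List of [cine_sequence()]s.
#' @param files Character vector of file paths (as referenced by the rows).
#' @param path Output CSV path.
#' @return The manifest data frame, invisibly.
#' @export
write_manifest <- function(seqs, files, path) {
  if (length(seqs) != length(files)) stop_invariant("one file per sequence required")
  rows <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    corr <- Filter(function(p) (p$op %||% "") %in%
                     c("corrupt_mistriggering", "corrupt_breathing"),
                   s$provenance)
    last <- if (length(corr)) corr[[length(corr)]] else NULL
    data.frame(file = files[i], label = s$label,
               seed = last$seed %||% NA_integer_,
               corruption_type = if (is.null(last)) NA_character_ else
                 sub("corrupt_", "", last$op),
               severity = last$z %||% last$amplitude_px %||% NA_real_)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset manifest
#'
#' @param path Manifest CSV path (columns `file`, `label`, ...).
#' @param check_files Verify that every referenced file exists.
#' @return The manifest data frame.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "label")
  if (!all(need %in% names(manifest))) {
    stop_invariant("manifest must have columns %s", paste(need, collapse = ", "))
  }
  if (check_files) {
    base <- dirname(path)
    missing <- manifest$file[!file.exists(manifest$file) &
                               !file.exists(file.path(base, manifest$file))]
    if (length(missing)) stop_invariant("manifest references missing file: %s",
                                        missing[1])
  }
  manifest
}

#' Save a model checkpoint
#'
#' Writes the trainable weights as an RDS file and a JSON sidecar
#' (`<path>.json`) holding the architecture spec and, optionally, the
#' training configuration — enough to rebuild and reload the model.
#'
#' @param state A `model_state`.
#' @param path Output path for the weight file (e.g. `model.rds`).
#' @param config Optional [train_config()] recorded in the sidecar.
#' @param force Overwrite an existing checkpoint.
#' @return `path`, invisibly.
#' @export
save_model <- function(state, path, config = NULL, force = FALSE) {
  if (!inherits(state, "model_state")) stop_invariant("`state` must be a `model_state`")
  if (file.exists(path) && !force) {
    stop_invariant("'%s' exists; use `force = TRUE` to overwrite", path)
  }
  saveRDS(list(weights = model_weights(state), training_log = state$training_log),
          path)
  jsonlite::write_json(list(spec = unclass(state$spec),
                            train_config = if (!is.null(config)) unclass(config)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model checkpoint
#'
#' Rebuilds the architecture from the JSON sidecar and restores the saved
#' weights.
#'
#' @param path Path given to [save_model()].
#' @return A `model_state`.
#' @export
load_model <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar)) {
    stop_invariant("checkpoint '%s' (or its .json sidecar) not found", path)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  sp <- meta$spec
  spec <- model_spec(architecture = sp$architecture,
                     input_shape = as.integer(sp$input_shape),
                     n_classes = as.integer(sp$n_classes),
                     conv_channels = as.integer(sp$conv_channels),
                     lstm_hidden = as.integer(sp$lstm_hidden),
                     fc_hidden = as.integer(sp$fc_hidden),
                     dropout_rate = sp$dropout_rate, init = sp$init)
  state <- build_model(spec, seed = 1L)
  blob <- readRDS(path)
  state <- set_model_weights(state, blob$weights)
  state$training_log <- blob$training_log
  state
}
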