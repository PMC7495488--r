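# Image and metadata I/O. Stacks are multi-frame single-channel TIFFs
# (32-bit float by default, so no commitment to a detector bit depth);
# acquisition metadata travels in a YAML sidecar next to each stack, and
# every CLI run writes a JSON manifest for reproducibility.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".yaml")

#' Write a multi-frame grayscale TIFF stack
#'
#' @param frames A matrix or list of matrices (identical dimensions).
#' @param path Output file.
#' @param metadata Optional named list written to a YAML sidecar
#'   (`<stem>.yaml`) next to the stack.
#' @param bits Bits per sample: 32 (float, default), 16 or 8 (integer;
#'   values must then lie in \[0, 1\]).
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(frames, path, metadata = NULL, bits = 32L) {
  if (is.matrix(frames)) frames <- list(frames)
  if (!length(frames) || !all(vapply(frames, is.matrix, TRUE))) {
    abort("`frames` must be a matrix or list of matrices",
          class = "carsdenoise_data_error")
  }
  # TIFF samples live in [0, 1]; out-of-range data is stored through an
  # affine map recorded in the sidecar and inverted on read.
  rng <- range(unlist(lapply(frames, range)))
  offset <- 0; scale <- 1
  if (rng[1] < 0 || rng[2] > 1) {
    offset <- rng[1]
    scale <- max(rng[2] - rng[1], .Machine$double.eps)
    frames <- lapply(frames, function(f) (f - offset) / scale)
    metadata <- c(metadata %||% list(),
                  list(value_offset = offset, value_scale = scale))
  }
  tiff::writeTIFF(frames, path, bits.per.sample = as.integer(bits))
  if (!is.null(metadata)) yaml::write_yaml(metadata, sidecar_path(path))
  invisible(path)
}

#' Read a multi-frame grayscale TIFF stack
#'
#' @param path A single-channel multi-frame TIFF.
#' @return A list with `frames` (list of matrices) and `metadata` (from the
#'   YAML sidecar; empty with a warning when no sidecar exists). RGB or
#'   multi-channel input is rejected.
#' @export
read_image_stack <- function(path) {
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE),
                     error = function(e) {
                       abort(sprintf("cannot read TIFF '%s': %s", path,
                                     conditionMessage(e)),
                             class = "carsdenoise_data_error")
                     })
  if (!is.list(frames)) frames <- list(frames)
  if (any(!vapply(frames, is.matrix, TRUE))) {
    abort("multi-channel (RGB) TIFF input is not supported",
          class = "carsdenoise_data_error")
  }
  meta <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- yaml::read_yaml(sp)
  } else {
    warn(sprintf("no metadata sidecar for '%s'; using defaults", path))
  }
  if (!is.null(meta$value_scale)) {
    frames <- lapply(frames, function(f)
      f * meta$value_scale + (meta$value_offset %||% 0))
  }
  list(frames = frames, metadata = meta)
}

#' Write a run manifest
#'
#' @param path Output JSON file.
#' @param command Name of the operation.
#' @param config Named list with the configuration snapshot (must include
#'   the seed).
#' @param inputs,outputs Character vectors of file paths; existing input
#'   files are checksummed (MD5).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config, inputs = character(),
                           outputs = character()) {
  checks <- if (length(inputs)) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  manifest <- list(command = command,
                   version = as.character(packageVersion("carsdenoise")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = config, input_checksums = checks,
                   outputs = as.list(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a simulated dataset to a directory
#'
#' One input stack (individual frames) and one target image per record,
#' each with a YAML sidecar carrying position, imaging rate, exposure and
#' seed.
#'
#' @param data A [simulate_dataset()] tibble with a `frames` column
#'   (`keep_frames = TRUE`).
#' @param dir Output directory (created if needed).
#' @param seed The generating seed (recorded in sidecars).
#' @return `dir`, invisibly.
#' @export
write_dataset_dir <- function(data, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_len(nrow(data))) {
    stem <- sprintf("pos%03d_n%03d", data$position[r], data$n_frames[r])
    meta <- list(position = data$position[r],
                 imaging_rate_ipm = data$imaging_rate_ipm[r],
                 frame_exposure_s = data$frame_exposure_s[r],
                 n_frames = data$n_frames[r], seed = seed)
    frames <- if ("frames" %in% names(data)) data$frames[[r]]
              else data$input[r]
    write_image_stack(frames, file.path(dir, paste0(stem, "_input.tif")),
                      metadata = meta)
    write_image_stack(data$target[[r]],
                      file.path(dir, paste0(stem, "_target.tif")),
                      metadata = c(meta, list(role = "ground_truth")))
  }
  invisible(dir)
}

#' Read a dataset directory
#'
#' @param dir A directory written by [write_dataset_dir()].
#' @return A tibble with `position`, `imaging_rate_ipm`, `frame_exposure_s`,
#'   `n_frames` and list-columns `input` (frame average) and `target`.
#' @export
read_dataset_dir <- function(dir) {
  inputs <- sort(list.files(dir, "_input\\.tif$", full.names = TRUE))
  if (!length(inputs)) {
    abort(sprintf("no input stacks found in '%s'", dir),
          class = "carsdenoise_data_error")
  }
  purrr::map_dfr(inputs, function(f) {
    st <- read_image_stack(f)
    tg <- read_image_stack(sub("_input\\.tif$", "_target.tif", f))
    md <- st$metadata
    tibble::tibble(position = md$position %||% NA_integer_,
                   imaging_rate_ipm = md$imaging_rate_ipm %||% NA_real_,
                   frame_exposure_s = md$frame_exposure_s %||% NA_real_,
                   n_frames = md$n_frames %||% length(st$frames),
                   input = list(Reduce(`+`, st$frames) / length(st$frames)),
                   target = list(tg$frames[[1]]))
  })
}
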