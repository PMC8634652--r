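#' Write a phantom (or any section stack) to disk
#'
#' Writes one multi-channel 16-bit TIFF per section (channel order dendrite,
#' axon, marker, recorded in the JSON sidecar), the ground-truth tables as
#' CSV, and the generating configuration as a JSON sidecar. Pixel values are
#' integer counts in [0, 65535]; the round trip through [read_phantom()] is
#' lossless.
#'
#' @param stack A `section_stack`.
#' @param truth Optional `phantom_truth` (omit for real data).
#' @param directory Output directory, created if missing.
#' @return Invisibly, the directory.
#' @export
write_phantom <- function(stack, truth = NULL, directory) {
  stopifnot(inherits(stack, "section_stack"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory, call. = FALSE)
  ny <- stack$dim[["ny"]]; nx <- stack$dim[["nx"]]
  for (k in seq_len(stack$n_sections)) {
    pl <- stack$sections[[k]]
    arr <- array(0, dim = c(ny, nx, length(stack$channels)))
    for (ci in seq_along(stack$channels))
      arr[, , ci] <- pl[[stack$channels[ci]]] / 65535
    tiff::writeTIFF(arr, file.path(directory, sprintf("section_%03d.tif", k)),
                    bits.per.sample = 16L, compression = "none")
  }
  meta <- list(n_sections = stack$n_sections,
               dim = list(ny = ny, nx = nx),
               channels = as.list(stack$channels),
               pixel_size_um = stack$pixel_size_um,
               section_thickness_um = stack$section_thickness_um)
  jsonlite::write_json(meta, file.path(directory, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    utils::write.csv(truth$synapses, file.path(directory, "synapses.csv"),
                     row.names = FALSE)
    utils::write.csv(truth$neurites, file.path(directory, "neurites.csv"),
                     row.names = FALSE)
    cfg <- truth$config
    jsonlite::write_json(unclass(cfg), file.path(directory, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(directory)
}

#' @rdname write_phantom
#' @return `read_phantom()` returns a list with `stack` and (when the truth
#'   CSVs are present) `truth`.
#' @export
read_phantom <- function(directory) {
  meta_path <- file.path(directory, "stack.json")
  if (!file.exists(meta_path))
    stop("no stack.json sidecar in ", directory, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  channels <- as.character(meta$channels)
  sections <- vector("list", meta$n_sections)
  for (k in seq_len(meta$n_sections)) {
    arr <- tiff::readTIFF(file.path(directory, sprintf("section_%03d.tif", k)))
    pl <- list()
    for (ci in seq_along(channels))
      pl[[channels[ci]]] <- matrix(round(arr[, , ci] * 65535),
                                   meta$dim$ny, meta$dim$nx)
    sections[[k]] <- pl
  }
  stack <- structure(list(
    sections = sections, n_sections = meta$n_sections,
    dim = c(ny = meta$dim$ny, nx = meta$dim$nx),
    channels = channels,
    pixel_size_um = meta$pixel_size_um,
    section_thickness_um = meta$section_thickness_um
  ), class = "section_stack")
  out <- list(stack = stack)
  syn_path <- file.path(directory, "synapses.csv")
  if (file.exists(syn_path)) {
    cfg_path <- file.path(directory, "config.json")
    cfg <- if (file.exists(cfg_path))
      structure(jsonlite::read_json(cfg_path, simplifyVector = TRUE),
                class = "phantom_config") else NULL
    out$truth <- structure(list(
      synapses = utils::read.csv(syn_path),
      neurites = utils::read.csv(file.path(directory, "neurites.csv")),
      config = cfg), class = "phantom_truth")
  }
  out
}
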