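# File interchange: decay-stack containers, 16-bit intensity TIFFs, and CSV
# tables. The decay container is an RDS-serialised named list with a fixed
# schema -- `counts[rows, cols, bins]`, `bin_edges` (ns), `channel`, and a
# `truth` record when the stack was simulated -- so stacks round-trip with
# their ground truth attached.

#' Write / read a decay-stack container
#'
#' @param image A `flim_image` (or a list with `stack`, `config`, `channel`,
#'   optionally `truth`).
#' @param path Output path (`.rds`).
#' @return `write_decay_container` returns `path` invisibly;
#'   `read_decay_container` returns a `flim_image`.
#' @export
write_decay_container <- function(image, path) {
  stopifnot(inherits(image, "flim_image"))
  obj <- list(counts = image$stack,
              bin_edges = bin_edges(image$config),
              channel = image$channel,
              truth = image$truth,
              config = image$config,
              mask_truth = image$mask_truth,
              seed = image$seed,
              format = "flimredox-decay-container-v1")
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_decay_container
#' @export
read_decay_container <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "flimredox-decay-container-v1")) {
    stop("not a flimredox decay container", call. = FALSE)
  }
  structure(
    list(stack = obj$counts,
         intensity = rowSums(obj$counts, dims = 2),
         mask_truth = obj$mask_truth, truth = obj$truth,
         config = obj$config, channel = obj$channel, seed = obj$seed),
    class = "flim_image"
  )
}

#' Write / read a 16-bit intensity TIFF
#'
#' Intensity images are photon counts; they are stored as single-channel
#' 16-bit TIFF, scaled by the recorded `max_count` so counts round-trip
#' exactly up to 16-bit quantisation of the stated maximum.
#'
#' @param intensity Numeric count matrix.
#' @param path Output path.
#' @return `write_intensity_tiff` returns `path` invisibly;
#'   `read_intensity_tiff` returns the count matrix.
#' @export
write_intensity_tiff <- function(intensity, path) {
  m <- max(intensity, 1)
  tiff::writeTIFF(intensity / m, path, bits.per.sample = 16L)
  # sidecar records the scale so counts are recoverable
  writeLines(format(m, digits = 17), paste0(path, ".scale"))
  invisible(path)
}

#' @rdname write_intensity_tiff
#' @export
read_intensity_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  scale_file <- paste0(path, ".scale")
  m <- if (file.exists(scale_file)) as.numeric(readLines(scale_file)) else 1
  round(img * m)
}
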