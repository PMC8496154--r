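#' Time-ordered grayscale image stack
#'
#' The universal raster container of the package: a `H x W x T` numeric
#' array of intensities in `[0, 1]` with physical calibration attached
#' (microns per pixel, seconds per frame).
#'
#' @param frames numeric array `H x W x T`, a single matrix (taken as
#'   `T = 1`), or a list of equally sized matrices.
#' @param pixel_um microns per pixel (> 0).
#' @param frame_interval_s seconds between frames (> 0).
#' @return an `image_stack` object.
#' @examples
#' s <- image_stack(array(runif(32 * 32 * 3), c(32, 32, 3)),
#'                  pixel_um = 1, frame_interval_s = 0.05)
#' dim(s)
#' @export
image_stack <- function(frames, pixel_um, frame_interval_s) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L)
      stop_bad_arg("all frames must have identical dimensions")
    frames <- array(unlist(frames), c(dims[[1L]], length(frames)))
  }
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop_bad_arg("`frames` must be an H x W x T array")
  if (!all(is.finite(frames)))
    stop_bad_arg("frame intensities must be finite")
  if (!is.numeric(pixel_um) || pixel_um <= 0)
    stop_bad_arg("`pixel_um` must be > 0")
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0)
    stop_bad_arg("`frame_interval_s` must be > 0")
  structure(frames, pixel_um = as.numeric(pixel_um),
            frame_interval_s = as.numeric(frame_interval_s),
            class = c("image_stack", "array"))
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<image_stack> %d x %d px, %d frame(s), %.3g um/px, %.4g s/frame\n",
    d[1], d[2], d[3], attr(x, "pixel_um"), attr(x, "frame_interval_s")))
  invisible(x)
}

n_frames <- function(stack) dim(stack)[3L]

get_frame <- function(stack, i) {
  f <- stack[, , i]
  dim(f) <- dim(stack)[1:2]
  f
}

#' Read a multi-page TIFF as an image stack
#'
#' Pages are read as floating point in `[0, 1]` (integer TIFFs are scaled
#' so the type maximum maps to 1).
#'
#' @param path path to a grayscale multi-page TIFF.
#' @param pixel_um,frame_interval_s physical calibration (the TIFF tags are
#'   not trusted for these).
#' @return an [image_stack()].
#' @export
read_stack <- function(path, pixel_um, frame_interval_s) {
  if (!file.exists(path)) stop_bad_arg(paste0("file not found: ", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # first channel of RGB pages
    p
  })
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L)
    stop_bad_arg("mixed page shapes in TIFF; refusing to read")
  image_stack(pages, pixel_um = pixel_um, frame_interval_s = frame_interval_s)
}

#' Write an image stack as a multi-page float TIFF
#'
#' @param stack an [image_stack()] (or plain matrix/array in `[0, 1]`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  pages <- lapply(seq_len(dim(stack)[3L]), function(i) get_frame(stack, i))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a single-frame grayscale image
#'
#' Convenience wrapper over [read_stack()] for still images (fiber,
#' ECM or coverage micrographs); returns a plain matrix in `[0, 1]`.
#'
#' @param path TIFF or PNG path.
#' @param channel channel index for multi-channel images.
#' @return numeric matrix.
#' @export
read_image <- function(path, channel = 1L) {
  if (!file.exists(path)) stop_bad_arg(paste0("file not found: ", path))
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , channel]
  img
}
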