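#' Time-lapse image stack
#'
#' Container for an ordered sequence of single-channel grayscale frames with
#' the acquisition metadata every downstream stage needs: the pixel size in
#' micrometres per pixel and the frame interval in minutes. Frames are stored
#' as numeric matrices indexed `[row = y, col = x]` with pixel centers at
#' integer coordinates, 0-based, x rightward and y downward; all public
#' outputs are converted to micrometres (or millimetres) with `pixel_size`.
#'
#' @param frames list of numeric matrices, all the same dimension, with
#'   intensities on the 16-bit grayscale range `[0, 65535]`.
#' @param pixel_size pixel size, um/px (> 0).
#' @param frame_interval time between consecutive frames, minutes (> 0).
#' @param channel label for the imaging channel, e.g. `"brightfield"` or
#'   `"beads"`.
#' @return An `image_stack` object.
#' @export
image_stack <- function(frames, pixel_size, frame_interval,
                        channel = "brightfield") {
  if (!is.list(frames) || length(frames) == 0L)
    stopf("`frames` must be a non-empty list of matrices")
  if (!all(vapply(frames, is.matrix, logical(1))))
    stopf("every frame must be a matrix")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("all frames must share the same shape")
  if (!is_num1(pixel_size) || pixel_size <= 0)
    stopf("`pixel_size` must be a positive number (um/px)")
  if (!is_num1(frame_interval) || frame_interval <= 0)
    stopf("`frame_interval` must be a positive number (minutes)")
  structure(
    list(frames = frames, pixel_size = pixel_size,
         frame_interval = frame_interval, channel = as.character(channel)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<image_stack> %d frame(s) of %d x %d px [%s]\n  pixel size %g um/px, frame interval %g min\n",
    length(x$frames), d[2], d[1], x$channel, x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack an [image_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) length(stack$frames)

#' Acquisition times of the frames
#' @param stack an [image_stack()].
#' @return Numeric vector of times in minutes, starting at 0.
#' @export
frame_times <- function(stack) (seq_along(stack$frames) - 1) * stack$frame_interval

#' Write a stack to a multi-page 16-bit TIFF
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  imgs <- lapply(stack$frames, function(m) m / BIT_DEPTH_MAX)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF into an image stack
#'
#' TIFF files carry no physical calibration here, so the pixel size and frame
#' interval must be supplied.
#'
#' @param path TIFF file path.
#' @inheritParams image_stack
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size, frame_interval,
                       channel = "brightfield") {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  frames <- lapply(imgs, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1]
    round(m * BIT_DEPTH_MAX)
  })
  image_stack(frames, pixel_size, frame_interval, channel)
}
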