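#' Calibrated image containers
#'
#' Light-weight containers tying luminance arrays to their physical
#' calibration. All downstream operators take physical parameters in
#' micrometres and convert through these calibrations, so that cut-offs
#' such as a 5 um^2 maximum component size or a 15 um overlap limit keep
#' their meaning across magnifications.
#'
#' * `calibrated_image()` — a single 2-D luminance matrix with a pixel
#'   size in um/px.
#' * `image_series()` — a time-lapse stack (row x col x frame array) with
#'   a frame interval in seconds.
#' * `zstack()` — an axial stack (row x col x slice array) with a z-step
#'   in um.
#'
#' Luminance must be finite and non-negative; calibrations must be
#' strictly positive.
#'
#' @param pixels numeric matrix of luminance values.
#' @param pixel_size pixel size, um/px.
#' @param frames 3-D numeric array, `[row, col, frame]`.
#' @param frame_interval time between frames, s.
#' @param slices 3-D numeric array, `[row, col, slice]`.
#' @param z_step axial step between slices, um.
#' @return An object of class `calibrated_image`, `image_series` or
#'   `zstack`.
#' @examples
#' img <- calibrated_image(matrix(runif(64), 8), pixel_size = 0.2)
#' img$pixel_size
#' @name containers
NULL

#' @rdname containers
#' @export
calibrated_image <- function(pixels, pixel_size) {
  pixels <- as.matrix(pixels)
  stopifnot(is.numeric(pixels), length(pixel_size) == 1L, pixel_size > 0)
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("luminance must be finite and >= 0")
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size)),
            class = "calibrated_image")
}

#' @rdname containers
#' @export
image_series <- function(frames, pixel_size, frame_interval) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L,
            dim(frames)[3] >= 1L, frame_interval > 0, pixel_size > 0)
  if (!all(is.finite(frames)) || any(frames < 0))
    stop("luminance must be finite and >= 0")
  structure(list(frames = frames, pixel_size = as.numeric(pixel_size),
                 frame_interval = as.numeric(frame_interval)),
            class = "image_series")
}

#' @rdname containers
#' @export
zstack <- function(slices, pixel_size, z_step) {
  stopifnot(is.array(slices), length(dim(slices)) == 3L, z_step > 0,
            pixel_size > 0)
  structure(list(slices = slices, pixel_size = as.numeric(pixel_size),
                 z_step = as.numeric(z_step)),
            class = "zstack")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %.4g um/px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size))
  invisible(x)
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_series> %d x %d px, %d frames @ %.3g s, %.4g um/px\n",
              d[1], d[2], d[3], x$frame_interval, x$pixel_size))
  invisible(x)
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf("<zstack> %d x %d px, %d slices @ %.3g um, %.4g um/px\n",
              d[1], d[2], d[3], x$z_step, x$pixel_size))
  invisible(x)
}

#' Extract one frame or slice as a calibrated image
#'
#' @param x an `image_series` or `zstack`.
#' @param i frame/slice index (1-based).
#' @return A `calibrated_image`.
#' @export
get_frame <- function(x, i) {
  arr <- if (inherits(x, "image_series")) x$frames else x$slices
  calibrated_image(arr[, , i, drop = TRUE], x$pixel_size)
}

#' Read and write calibrated multi-page TIFF
#'
#' Images travel as grayscale multi-page TIFF (16-bit by default, values
#' scaled to the `[0, 1]` range the `tiff` package uses) with the physical
#' calibration in a JSON sidecar (`<file>.json`), since baseline TIFF
#' tags cannot carry frame intervals or z-steps.
#'
#' @param x a `calibrated_image`, `image_series` or `zstack`.
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @return `write_tiff()` returns `path` invisibly; `read_tiff()` returns
#'   the container described by the sidecar.
#' @export
write_tiff <- function(x, path) {
  arr <- switch(class(x)[1],
    calibrated_image = array(x$pixels, c(dim(x$pixels), 1L)),
    image_series = x$frames,
    zstack = x$slices,
    stop("unsupported container"))
  hi <- max(arr, 1e-12)
  pages <- lapply(seq_len(dim(arr)[3]), function(i) arr[, , i] / hi)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(class = class(x)[1], pixel_size = x$pixel_size, scale = hi,
               frame_interval = x$frame_interval, z_step = x$z_step)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tiff
#' @export
read_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]] * meta$scale
  switch(meta$class,
    calibrated_image = calibrated_image(arr[, , 1], meta$pixel_size),
    image_series = image_series(arr, meta$pixel_size, meta$frame_interval),
    zstack = zstack(arr, meta$pixel_size, meta$z_step),
    stop("unknown container class in sidecar"))
}
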