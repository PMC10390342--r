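#' Time-lapse image stack with physical metadata
#'
#' A thin container for a T-frame single-channel image series: a numeric
#' array indexed `[row, col, frame]` plus the pixel size (um/px) and frame
#' interval (min/frame) needed to express PIV output in physical units.
#' Rows increase with image y, columns with image x; the anteroposterior
#' (AP) axis maps to image x, with x increasing head-to-tail by convention.
#'
#' @param data numeric array `[H, W, T]` (a matrix is treated as one frame).
#' @param pixel_size_um pixel size in micrometres per pixel.
#' @param frame_interval_min time between frames in minutes.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size_um, frame_interval_min) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L,
            pixel_size_um > 0, frame_interval_min > 0)
  structure(list(data = data,
                 pixel_size_um = as.numeric(pixel_size_um),
                 frame_interval_min = as.numeric(frame_interval_min)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d x %d px, %d frame(s), %.3g um/px, %.3g min/frame\n",
              d[1], d[2], d[3], x$pixel_size_um, x$frame_interval_min))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' Read a multi-page TIFF as an image stack
#'
#' @param path TIFF file path.
#' @inheritParams image_stack
#' @return an [image_stack].
#' @export
read_image_stack <- function(path, pixel_size_um, frame_interval_min) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  arr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  image_stack(arr, pixel_size_um, frame_interval_min)
}

#' Write an image stack to a multi-page TIFF
#'
#' Intensities are rescaled to `[0, 1]` for storage (TIFF float pages keep
#' relative structure; absolute units are not preserved).
#'
#' @param stack an [image_stack].
#' @param path output file path.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- stack$data
  rng <- range(d)
  if (diff(rng) > 0) d <- (d - rng[1]) / diff(rng)
  pages <- lapply(seq_len(dim(d)[3]), function(t) d[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}
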