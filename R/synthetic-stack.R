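#' Parameters for synthetic speckle stack rendering
#'
#' Describes a textured (speckled) tissue surface stand-in for the
#' collagen-IV surface signal: random bright points blurred to Gaussian
#' blobs, advected frame-to-frame by a prescribed flow, with optional
#' photobleaching and additive read noise.
#'
#' @param image_shape `(H, W)` in pixels.
#' @param pixel_size_um um per pixel.
#' @param frame_interval_min minutes per frame.
#' @param n_frames number of frames (>= 1).
#' @param speckle_density fraction of seed pixels set bright, in (0, 1).
#' @param speckle_sigma Gaussian blob sigma in pixels.
#' @param noise_sd additive Gaussian noise sd as a fraction of the mean
#'   frame-0 intensity.
#' @param bleach_rate exponential intensity decay rate (1/min).
#' @param seed integer RNG seed.
#' @return object of class `speckle_params`.
#' @export
speckle_params <- function(image_shape = c(128, 128), pixel_size_um = 0.5,
                           frame_interval_min = 1, n_frames = 2,
                           speckle_density = 0.02, speckle_sigma = 1.5,
                           noise_sd = 0, bleach_rate = 0, seed = 1) {
  stopifnot(all(image_shape > 0), pixel_size_um > 0, frame_interval_min > 0,
            n_frames >= 1, speckle_density > 0, speckle_density < 1,
            speckle_sigma > 0, noise_sd >= 0, bleach_rate >= 0)
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min,
                 n_frames = as.integer(n_frames),
                 speckle_density = speckle_density,
                 speckle_sigma = speckle_sigma,
                 noise_sd = noise_sd, bleach_rate = bleach_rate,
                 seed = as.integer(seed)),
            class = "speckle_params")
}

# Bilinear sample of matrix `img` at fractional pixel coords (ri, ci),
# 1-based; outside the domain returns 0.
bilinear_sample <- function(img, ri, ci) {
  h <- nrow(img); w <- ncol(img)
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  get_px <- function(r, c) {
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    v <- numeric(length(r))
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  get_px(r0, c0) * (1 - fr) * (1 - fc) +
    get_px(r0 + 1, c0) * fr * (1 - fc) +
    get_px(r0, c0 + 1) * (1 - fr) * fc +
    get_px(r0 + 1, c0 + 1) * fr * fc
}

#' Render a speckle stack advected by a prescribed flow
#'
#' Frame 1 is a random Gaussian-blob speckle texture. Each subsequent frame
#' is the previous frame advected by the flow integrated over one frame
#' interval (backward mapping with bilinear interpolation), multiplied by
#' `exp(-bleach_rate * dt)`, plus additive Gaussian noise clipped at zero.
#' Identical seeds and parameters give bit-identical stacks.
#'
#' @param flow a flow field function from [generate_flow_field()], in um/min.
#' @param params a [speckle_params].
#' @param piv_params optional [piv_params]; if supplied, a warning is issued
#'   when the per-frame displacement can exceed half the PIV search margin.
#' @return an [image_stack].
#' @export
render_speckle_stack <- function(flow, params, piv_params = NULL) {
  stopifnot(inherits(params, "speckle_params"))
  h <- params$image_shape[1]; w <- params$image_shape[2]
  ps <- params$pixel_size_um; dt <- params$frame_interval_min

  # pixel-center physical coordinates: x along columns, y along rows,
  # pixel centers at integer um multiples of the pixel size (0-based)
  xs <- (seq_len(w) - 1) * ps
  ys <- (seq_len(h) - 1) * ps
  cx <- matrix(rep(xs, each = h), h, w)
  cy <- matrix(rep(ys, times = w), h, w)

  if (!is.null(piv_params)) {
    v <- flow(as.vector(cx), as.vector(cy), 0)
    dmax <- max(sqrt(v$u^2 + v$v^2)) * dt
    margin <- (piv_params$search_size - piv_params$source_size) / 2
    if (dmax > margin)
      warning(sprintf(paste0("per-frame displacement %.2f um exceeds the PIV",
                             " search margin %.2f um"), dmax, margin))
  }

  arr <- array(0, c(h, w, params$n_frames))
  arr[, , 1] <- with_seed(params$seed, {
    seeds <- matrix(stats::runif(h * w) < params$speckle_density, h, w)
    img <- matrix(0, h, w)
    img[seeds] <- 1
    img <- EBImage::gblur(img, sigma = params$speckle_sigma)
    img / max(img)
  })
  mean0 <- mean(arr[, , 1])

  if (params$n_frames > 1) {
    noise <- with_seed(params$seed + 1L, {
      if (params$noise_sd > 0)
        array(stats::rnorm(h * w * (params$n_frames - 1), 0,
                           params$noise_sd * mean0),
              c(h, w, params$n_frames - 1))
      else array(0, c(h, w, params$n_frames - 1))
    })
    for (t in seq_len(params$n_frames - 1)) {
      v <- flow(as.vector(cx), as.vector(cy), (t - 1) * dt)
      # backward map: source position = target - displacement
      src_c <- (as.vector(cx) - v$u * dt) / ps + 1
      src_r <- (as.vector(cy) - v$v * dt) / ps + 1
      warped <- matrix(bilinear_sample(arr[, , t], src_r, src_c), h, w)
      warped <- warped * exp(-params$bleach_rate * dt) + noise[, , t]
      arr[, , t + 1] <- pmax(warped, 0)
    }
  }
  image_stack(arr, ps, dt)
}
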