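#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards. All generators take explicit seeds and
# never leak into (or depend on) global RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Centered moving average with shrinking edge windows
#'
#' Walking (moving) average used throughout the pipeline for trace and
#' profile smoothing. The window is centered; near the edges it shrinks so
#' the output has the same length as the input. `NA` values are dropped from
#' each window; a window with no finite value yields `NA`.
#'
#' @param x numeric vector.
#' @param window window size in samples (full width).
#' @return numeric vector of `length(x)`.
#' @export
moving_average <- function(x, window) {
  stopifnot(window >= 1)
  n <- length(x)
  if (n == 0L) return(x)
  half_lo <- floor((window - 1) / 2)
  half_hi <- ceiling((window - 1) / 2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half_lo):min(n, i + half_hi)
    v <- x[j]
    v <- v[is.finite(v)]
    out[i] <- if (length(v)) mean(v) else NA_real_
  }
  out
}

# Round a physical window size (um) to the nearest odd pixel count (>= 3),
# so correlation windows have a well-defined center pixel.
um_to_odd_px <- function(size_um, pixel_size_um) {
  px <- size_um / pixel_size_um
  odd <- 2 * round((px - 1) / 2) + 1
  max(odd, 3L)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
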