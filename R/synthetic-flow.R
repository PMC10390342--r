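#' Prescribed tissue-surface flow specification
#'
#' Ground-truth flow fields for PIV validation and track generation. The
#' `tail_to_head_gradient` kind emulates the coherent long-range collagen-IV
#' flow observed on the condensing nerve cord: speed is maximal at the tail
#' end of the tissue and decays linearly head-ward.
#'
#' @param kind one of `"uniform"`, `"tail_to_head_gradient"`, `"rotational"`,
#'   `"zero"`.
#' @param peak_speed peak flow speed (um/min), >= 0.
#' @param gradient_length length scale (um) over which speed decays to zero
#'   head-ward of the tail (gradient kind only).
#' @param axis unit 2-vector giving the tail-to-head direction of motion.
#' @return an object of class `flow_spec`.
#' @export
flow_spec <- function(kind = c("uniform", "tail_to_head_gradient",
                               "rotational", "zero"),
                      peak_speed = 1, gradient_length = 100,
                      axis = c(-1, 0)) {
  kind <- match.arg(kind)
  stopifnot(peak_speed >= 0, gradient_length > 0, length(axis) == 2L)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop_config("flow axis must be a non-zero 2-vector")
  structure(list(kind = kind, peak_speed = peak_speed,
                 gradient_length = gradient_length, axis = axis / nrm),
            class = "flow_spec")
}

#' Evaluate a flow specification as a displacement-rate field
#'
#' Returns a vectorised function `f(x, y, t)` giving the local velocity in
#' um/min at positions in um. For the gradient kind, the tail end is the
#' domain corner at which the projection onto the motion axis is minimal
#' (motion is tail-to-head, so tail = most "upstream" point of the domain);
#' speed ramps down linearly from `peak_speed` there over `gradient_length`,
#' clamped at zero.
#'
#' @param spec a [flow_spec].
#' @param stack_geometry list with `width_um` and `height_um` giving the
#'   image domain extent (needed for the gradient and rotational kinds).
#' @return function `(x, y, t) -> list(u =, v =)` in um/min.
#' @export
generate_flow_field <- function(spec, stack_geometry = list(width_um = 100,
                                                            height_um = 100)) {
  stopifnot(inherits(spec, "flow_spec"))
  ax <- spec$axis
  w <- stack_geometry$width_um
  h <- stack_geometry$height_um
  switch(spec$kind,
    zero = function(x, y, t) list(u = rep(0, length(x)), v = rep(0, length(x))),
    uniform = function(x, y, t) {
      list(u = rep(spec$peak_speed * ax[1], length(x)),
           v = rep(spec$peak_speed * ax[2], length(x)))
    },
    tail_to_head_gradient = {
      # projection of domain corners onto the motion axis; tail = minimum
      corners_proj <- c(0, w * ax[1], h * ax[2], w * ax[1] + h * ax[2])
      p0 <- min(corners_proj)
      function(x, y, t) {
        s <- (x * ax[1] + y * ax[2]) - p0   # um from the tail end
        sp <- spec$peak_speed * pmax(0, 1 - s / spec$gradient_length)
        list(u = sp * ax[1], v = sp * ax[2])
      }
    },
    rotational = {
      cx <- w / 2; cy <- h / 2
      function(x, y, t) {
        r <- sqrt((x - cx)^2 + (y - cy)^2)
        r[r == 0] <- Inf
        omega <- spec$peak_speed / max(w, h) * 2   # rad/min, peak at domain edge
        list(u = -omega * (y - cy), v = omega * (x - cx))
      }
    },
    stop_config("unknown flow kind '%s'", spec$kind))
}
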