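#' Filter tracks and split by region and phase window
#'
#' Restricts each track to the requested time windows, keeps those whose
#' within-window portion has more than `min_frames` samples (strictly
#' greater, i.e. at least `min_frames + 1`), and assigns each retained
#' track to the head or tail region by its mean anteroposterior position
#' relative to `region_boundary_um` (x increases head-to-tail, so mean
#' x below the boundary means head).
#'
#' @param tracks data.frame `track_id, frame, x_um, y_um`.
#' @param min_frames minimum sample count threshold (default 10; tracks
#'   must be strictly longer).
#' @param windows list of `(t_start, t_end)` minute pairs; defaults to the
#'   two 3-h condensation windows 0-180 and 420-600 min.
#' @param region_boundary_um AP coordinate separating head (smaller x)
#'   from tail.
#' @param frame_interval_min minutes per frame (default 10).
#' @return named list of track tables, one per `window<i>_<region>`
#'   combination; empty windows warn.
#' @export
filter_and_window_tracks <- function(tracks, min_frames = 10,
                                     windows = list(c(0, 180), c(420, 600)),
                                     region_boundary_um = 100,
                                     frame_interval_min = 10) {
  stopifnot(all(c("track_id", "frame", "x_um", "y_um") %in% names(tracks)))
  t_min <- (tracks$frame - min(tracks$frame)) * frame_interval_min
  out <- list()
  for (w in seq_along(windows)) {
    win <- windows[[w]]
    in_win <- t_min >= win[1] & t_min <= win[2]
    if (!any(in_win)) {
      warning(sprintf("window %g-%g min is outside the recording", win[1], win[2]))
      out[[sprintf("window%d_head", w)]] <- tracks[0, ]
      out[[sprintf("window%d_tail", w)]] <- tracks[0, ]
      next
    }
    sub <- tracks[in_win, , drop = FALSE]
    counts <- table(sub$track_id)
    keep <- names(counts)[counts > min_frames]
    sub <- sub[sub$track_id %in% keep, , drop = FALSE]
    mean_x <- tapply(sub$x_um, sub$track_id, mean)
    head_ids <- names(mean_x)[mean_x < region_boundary_um]
    out[[sprintf("window%d_head", w)]] <-
      sub[sub$track_id %in% head_ids, , drop = FALSE]
    out[[sprintf("window%d_tail", w)]] <-
      sub[!(sub$track_id %in% head_ids), , drop = FALSE]
  }
  out
}

#' Start-to-end directionality summary of a track set
#'
#' Draws a vector from each track's first to last position and reports its
#' angle with zero on the horizontal head-to-tail axis (+x), increasing
#' counter-clockwise, in `[0, 2*pi)`; a polar histogram of those angles;
#' and the mean average velocity, i.e. the mean over tracks of total path
#' length divided by track duration. Tracks with zero net displacement
#' have no defined angle: they are excluded from the histogram and counted
#' in `n_zero`.
#'
#' @param track_set data.frame `track_id, frame, x_um, y_um`.
#' @param bin_width_deg polar histogram bin width (default 20 degrees).
#' @param frame_interval_min minutes per frame.
#' @return object of class `track_directionality`: list with `angles_rad`
#'   (named by track), `histogram` (counts per bin), `breaks_rad`,
#'   `n_tracks`, `n_zero`, `mean_velocity_um_min`, and the circular mean
#'   resultant length `resultant_length`.
#' @export
track_directionality <- function(track_set, bin_width_deg = 20,
                                 frame_interval_min = 10) {
  ids <- unique(track_set$track_id)
  if (length(ids) == 0L)
    return(structure(list(angles_rad = numeric(0),
                          histogram = integer(0), breaks_rad = numeric(0),
                          n_tracks = 0L, n_zero = 0L,
                          mean_velocity_um_min = NA_real_,
                          resultant_length = NA_real_),
                     class = "track_directionality"))
  per <- lapply(ids, function(id) {
    tr <- track_set[track_set$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    dx <- tr$x_um[nrow(tr)] - tr$x_um[1]
    dy <- tr$y_um[nrow(tr)] - tr$y_um[1]
    path <- sum(sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2))
    dur <- (tr$frame[nrow(tr)] - tr$frame[1]) * frame_interval_min
    list(dx = dx, dy = dy, path = path, dur = dur)
  })
  dx <- vapply(per, `[[`, numeric(1), "dx")
  dy <- vapply(per, `[[`, numeric(1), "dy")
  nonzero <- (dx^2 + dy^2) > 0
  ang <- atan2(dy[nonzero], dx[nonzero]) %% (2 * pi)
  names(ang) <- ids[nonzero]
  breaks <- seq(0, 2 * pi, by = bin_width_deg * pi / 180)
  if (breaks[length(breaks)] < 2 * pi) breaks <- c(breaks, 2 * pi)
  hist_counts <- as.integer(table(cut(ang, breaks, right = FALSE,
                                      include.lowest = TRUE)))
  vel <- vapply(per, function(p) p$path / p$dur, numeric(1))
  R <- if (length(ang)) sqrt(mean(cos(ang))^2 + mean(sin(ang))^2) else NA_real_
  structure(list(angles_rad = ang, histogram = hist_counts,
                 breaks_rad = breaks, n_tracks = sum(nonzero),
                 n_zero = sum(!nonzero),
                 mean_velocity_um_min = mean(vel),
                 resultant_length = R),
            class = "track_directionality")
}
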