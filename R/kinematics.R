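#' Construct a point track
#'
#' A `point_track` is the 2D trajectory of one derived effector (palm,
#' paretic shoulder, or trunk) within a block: ordered pixel positions, the
#' original frame indices they came from, and the sampling rate.
#'
#' @param label One of `"palm"`, `"shoulder"`, `"trunk"`.
#' @param x,y Numeric vectors of equal length (pixels, finite).
#' @param fps Sampling rate (Hz), equal to the source series fps.
#' @param frame Integer frame indices (strictly increasing); defaults to
#'   `seq_along(x)`. Gaps in `frame` mark frames dropped upstream.
#' @return An object of class `point_track`.
#' @export
point_track <- function(label, x, y, fps, frame = seq_along(x)) {
  label <- match.arg(label, c("palm", "shoulder", "trunk"))
  if (length(x) != length(y) || length(x) != length(frame)) {
    stop("`x`, `y` and `frame` must have equal length", call. = FALSE)
  }
  if (length(x) < 1L) {
    stop("a point track needs at least one point", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("track coordinates must be finite", call. = FALSE)
  }
  if (!is.numeric(fps) || fps <= 0) {
    stop("`fps` must be positive", call. = FALSE)
  }
  if (is.unsorted(frame, strictly = TRUE)) {
    stop("`frame` must be strictly increasing", call. = FALSE)
  }
  structure(list(label = label, x = as.numeric(x), y = as.numeric(y),
                 fps = as.numeric(fps), frame = as.integer(frame)),
            class = "point_track")
}

#' @export
print.point_track <- function(x, ...) {
  cat(sprintf("<point_track> %s: %d points @ %g fps\n",
              x$label, length(x$x), x$fps))
  invisible(x)
}

series_xy <- function(series, lm) {
  list(x = series$data[[paste0(lm, "_x")]],
       y = series$data[[paste0(lm, "_y")]])
}

check_nonempty <- function(series) {
  if (nrow(series$data) == 0L) {
    stop("landmark series has no frames", call. = FALSE)
  }
}

#' Palm trajectory: centroid of pinky, index and wrist
#'
#' The palm effector is defined per frame as the arithmetic mean of the
#' pinky-finger, index-finger and wrist landmark positions.
#'
#' @param series A preprocessed [landmark_series()] (no missing samples).
#' @return A [point_track()] labelled `"palm"`.
#' @export
palm_track <- function(series) {
  stopifnot(inherits(series, "landmark_series"))
  check_nonempty(series)
  p <- series_xy(series, "pinky")
  i <- series_xy(series, "index")
  w <- series_xy(series, "wrist")
  point_track("palm",
              (p$x + i$x + w$x) / 3, (p$y + i$y + w$y) / 3,
              series$fps, series$data$frame)
}

#' Trunk trajectory: centroid of both shoulders and both hips
#'
#' The trunk effector is defined per frame as the arithmetic mean of the
#' left/right shoulder and left/right hip landmark positions.
#'
#' @inheritParams palm_track
#' @return A [point_track()] labelled `"trunk"`.
#' @export
trunk_track <- function(series) {
  stopifnot(inherits(series, "landmark_series"))
  check_nonempty(series)
  sl <- series_xy(series, "shoulder_left")
  sr <- series_xy(series, "shoulder_right")
  hl <- series_xy(series, "hip_left")
  hr <- series_xy(series, "hip_right")
  point_track("trunk",
              (sl$x + sr$x + hl$x + hr$x) / 4,
              (sl$y + sr$y + hl$y + hr$y) / 4,
              series$fps, series$data$frame)
}

#' Paretic-shoulder trajectory
#'
#' Returns the positions of the shoulder landmark on the given (paretic)
#' side, unmodified.
#'
#' @inheritParams palm_track
#' @param side `"L"` or `"R"`: which shoulder to extract.
#' @return A [point_track()] labelled `"shoulder"`.
#' @export
shoulder_track <- function(series, side) {
  stopifnot(inherits(series, "landmark_series"))
  check_nonempty(series)
  side <- match.arg(side, c("L", "R"))
  lm <- if (side == "L") "shoulder_left" else "shoulder_right"
  s <- series_xy(series, lm)
  point_track("shoulder", s$x, s$y, series$fps, series$data$frame)
}

#' Bivariate variable error (BVE)
#'
#' BVE summarizes positional variability about the centroid of a 2D point
#' set: the root mean squared Euclidean deviation
#' \deqn{BVE = \sqrt{\frac{1}{n}\sum_{i=1}^{n}\big((x_i-x_c)^2 + (y_i-y_c)^2\big)}}
#' where \eqn{(x_c, y_c)} is the component-wise mean of the points
#' themselves. The normalization is 1/n (population form), so
#' \eqn{BVE^2} equals the population variance of x plus the population
#' variance of y. BVE is invariant to translation and rotation and scales
#' linearly with a uniform rescaling of coordinates. Here it is computed
#' over the continuous position data of a whole block, not over per-trial
#' endpoints.
#'
#' @param track A [point_track()] with at least one point.
#' @return Non-negative scalar, in pixels.
#' @export
bve <- function(track) {
  stopifnot(inherits(track, "point_track"))
  n <- length(track$x)
  if (n < 1L) stop("cannot compute BVE of an empty track", call. = FALSE)
  dx <- track$x - mean(track$x)
  dy <- track$y - mean(track$y)
  sqrt(mean(dx^2 + dy^2))
}

#' Framewise speed of a track
#'
#' Speed at frame f is the Euclidean distance travelled between frames f-1
#' and f divided by the elapsed time, which is exactly `1/fps` (per-sample
#' timestamps are not used). For a track of n points this yields n-1
#' non-negative values in pixels/second.
#'
#' @param track A [point_track()] with at least two points.
#' @return Numeric vector of length n-1.
#' @export
framewise_speed <- function(track) {
  stopifnot(inherits(track, "point_track"))
  n <- length(track$x)
  if (n < 2L) {
    stop("framewise speed needs at least 2 frames", call. = FALSE)
  }
  sqrt(diff(track$x)^2 + diff(track$y)^2) * track$fps
}

#' Mean landmark speed
#'
#' The arithmetic mean of the framewise speeds of a track. When frames were
#' dropped upstream (gaps in the track's frame indices), the apparent jump
#' across a gap does not reflect motion over a single frame interval; by
#' default such gap-spanning steps are excluded from the mean.
#'
#' @inheritParams framewise_speed
#' @param exclude_gaps If `TRUE` (default), steps between non-consecutive
#'   frame indices are excluded from the mean.
#' @return Non-negative scalar, pixels/second.
#' @export
mean_speed <- function(track, exclude_gaps = TRUE) {
  speeds <- framewise_speed(track)
  if (exclude_gaps) {
    keep <- diff(track$frame) == 1L
    if (!any(keep)) {
      stop("no consecutive-frame steps remain after gap exclusion",
           call. = FALSE)
    }
    speeds <- speeds[keep]
  }
  mean(speeds)
}
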