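#' Construct a landmark series
#'
#' A `landmark_series` holds the time-indexed 2D positions (and per-sample
#' visibility confidence) of the eight tracked landmarks for one block
#' recording of one participant on one day. Coordinates are in pixels using
#' image convention (origin top-left, y increases downward); `fps` is the
#' constant sampling rate, so the elapsed time between consecutive frames is
#' exactly `1/fps` seconds.
#'
#' @param participant_id Participant identifier (string).
#' @param day Session number (integer).
#' @param block Block number within the session (integer).
#' @param fps Frames per second (Hz), strictly positive.
#' @param data Tibble with one row per frame: an integer `frame` column
#'   (strictly increasing) and, for each landmark name `L` in
#'   [landmark_names()], columns `L_x`, `L_y` (pixels, finite) and `L_v`
#'   (visibility in \[0, 1\]).
#' @param n_interpolated,n_dropped Frame counts recorded by [preprocess()];
#'   zero for raw series.
#' @return An object of class `landmark_series`.
#' @export
landmark_series <- function(participant_id, day, block, fps, data,
                            n_interpolated = 0L, n_dropped = 0L) {
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop("`fps` must be a single positive number", call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  needed <- c("frame", landmark_cols())
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0L) {
    stop("landmark series data is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) > 0L) {
    if (is.unsorted(data$frame, strictly = TRUE)) {
      stop("`frame` must be strictly increasing", call. = FALSE)
    }
    xy <- as.matrix(data[grep("_(x|y)$", names(data), value = TRUE)])
    if (!all(is.finite(xy))) {
      stop("landmark coordinates must be finite", call. = FALSE)
    }
    v <- as.matrix(data[grep("_v$", names(data), value = TRUE)])
    if (any(v < 0 | v > 1, na.rm = TRUE) || anyNA(v)) {
      stop("visibility values must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(participant_id = as.character(participant_id),
         day = as.integer(day), block = as.integer(block),
         fps = as.numeric(fps),
         data = data[, needed],
         n_interpolated = as.integer(n_interpolated),
         n_dropped = as.integer(n_dropped)),
    class = "landmark_series"
  )
}

landmark_cols <- function() {
  as.vector(vapply(landmark_names(),
                   function(l) paste0(l, c("_x", "_y", "_v")),
                   character(3)))
}

#' @export
print.landmark_series <- function(x, ...) {
  cat(sprintf(
    "<landmark_series> participant %s, day %d, block %d: %d frames @ %g fps\n",
    x$participant_id, x$day, x$block, nrow(x$data), x$fps))
  if (x$n_interpolated > 0L || x$n_dropped > 0L) {
    cat(sprintf("  preprocessing: %d frames interpolated, %d dropped\n",
                x$n_interpolated, x$n_dropped))
  }
  invisible(x)
}

#' Number of frames in a landmark series
#' @param series A [landmark_series()].
#' @return Integer frame count.
#' @export
n_frames <- function(series) {
  stopifnot(inherits(series, "landmark_series"))
  nrow(series$data)
}

#' Read landmark time series from CSV
#'
#' Reads the package's long landmark CSV dialect: UTF-8, comma-separated,
#' header `participant_id,day,block,frame,fps,landmark,x,y,visibility`, one
#' row per (frame, landmark) sample. Rows are grouped into one
#' [landmark_series()] per (participant, day, block), with frames sorted by
#' frame index.
#'
#' @param path Path to a CSV file written by [write_landmark_csv()] (or any
#'   file in the same dialect).
#' @param frame_range Optional length-2 integer vector `c(first, last)`;
#'   frames outside this range are discarded on read (recordings are
#'   otherwise assumed pre-trimmed to the task interval).
#' @return A list of [landmark_series()] objects, ordered by participant,
#'   day, block.
#' @export
read_landmark_csv <- function(path, frame_range = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "day", "block", "frame", "fps",
                "landmark", "x", "y", "visibility")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("landmark CSV is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    return(list())
  }
  unknown <- setdiff(unique(df$landmark), landmark_names())
  if (length(unknown) > 0L) {
    stop("unknown landmark name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(frame_range)) {
    stopifnot(length(frame_range) == 2L)
    df <- df[df$frame >= frame_range[1] & df$frame <= frame_range[2], ]
  }
  groups <- split(df, interaction(df$participant_id, df$day, df$block,
                                  drop = TRUE, lex.order = TRUE))
  out <- lapply(groups, function(g) {
    fps <- unique(g$fps)
    if (length(fps) != 1L) {
      stop(sprintf("fps is not constant within participant %s day %d block %d",
                   g$participant_id[1], g$day[1], g$block[1]), call. = FALSE)
    }
    wide <- tidyr::pivot_wider(
      tibble::as_tibble(g[c("frame", "landmark", "x", "y", "visibility")]),
      names_from = "landmark",
      values_from = c("x", "y", "visibility"),
      names_glue = "{landmark}_{substr(.value, 1, 1)}"
    )
    wide <- wide[order(wide$frame), ]
    landmark_series(g$participant_id[1], g$day[1], g$block[1], fps, wide)
  })
  names(out) <- NULL
  out[order(vapply(out, function(s) s$participant_id, character(1)),
            vapply(out, function(s) s$day, integer(1)),
            vapply(out, function(s) s$block, integer(1)))]
}

#' Write landmark time series to CSV
#'
#' Serializes a collection of [landmark_series()] to the long CSV dialect
#' read by [read_landmark_csv()]. Coordinates are written with full double
#' precision (15 significant digits), so a write/read round trip reproduces
#' values well beyond 9 significant digits.
#'
#' @param series A [landmark_series()] or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landmark_csv <- function(series, path) {
  if (inherits(series, "landmark_series")) series <- list(series)
  stopifnot(all(vapply(series, inherits, logical(1), "landmark_series")))
  rows <- lapply(series, function(s) {
    long <- tidyr::pivot_longer(
      s$data, cols = -"frame",
      names_to = c("landmark", ".value"),
      names_pattern = "^(.*)_([xyv])$"
    )
    tibble::tibble(participant_id = s$participant_id, day = s$day,
                   block = s$block, frame = long$frame, fps = s$fps,
                   landmark = long$landmark, x = long$x, y = long$y,
                   visibility = long$v)
  })
  out <- if (length(rows) > 0L) dplyr::bind_rows(rows) else
    tibble::tibble(participant_id = character(), day = integer(),
                   block = integer(), frame = integer(), fps = numeric(),
                   landmark = character(), x = numeric(), y = numeric(),
                   visibility = numeric())
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("could not write landmark CSV to ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

#' Interpolate low-visibility samples and drop unusable frames
#'
#' Treats landmark samples whose visibility confidence falls below
#' `visibility_threshold` as missing. Missing runs of at most `max_gap`
#' consecutive frames that are flanked by observed samples are filled by
#' linear interpolation against the frame index (interpolated samples get
#' visibility equal to the threshold); frames in which any landmark is still
#' missing afterwards are dropped. No frames are ever invented: output frame
#' indices are a subset of the input's. With `visibility_threshold = 0` the
#' series is returned unchanged.
#'
#' @param series A [landmark_series()].
#' @param visibility_threshold Samples with visibility strictly below this
#'   value (default 0.5) are treated as missing.
#' @param max_gap Longest run of consecutive missing frames (default 5) that
#'   is repaired by linear interpolation; longer runs, and runs touching the
#'   series boundary, are dropped instead.
#' @return A [landmark_series()] with no sample below the threshold, and the
#'   counts of interpolated and dropped frames recorded in
#'   `n_interpolated` / `n_dropped` (added to any counts already present).
#' @export
preprocess <- function(series, visibility_threshold = 0.5, max_gap = 5L) {
  stopifnot(inherits(series, "landmark_series"))
  stopifnot(visibility_threshold >= 0, visibility_threshold <= 1, max_gap >= 0)
  data <- series$data
  n <- nrow(data)
  if (n == 0L) {
    stop("cannot preprocess an empty landmark series", call. = FALSE)
  }
  if (visibility_threshold == 0) {
    return(series)
  }
  interpolated <- logical(n)
  for (lm in landmark_names()) {
    vcol <- paste0(lm, "_v")
    miss <- data[[vcol]] < visibility_threshold
    if (!any(miss)) next
    runs <- rle(miss)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      len <- i1 - i0 + 1L
      if (len <= max_gap && i0 > 1L && i1 < n) {
        f <- data$frame
        for (coord in c("_x", "_y")) {
          col <- paste0(lm, coord)
          lo <- data[[col]][i0 - 1L]; hi <- data[[col]][i1 + 1L]
          w <- (f[i0:i1] - f[i0 - 1L]) / (f[i1 + 1L] - f[i0 - 1L])
          data[[col]][i0:i1] <- lo + w * (hi - lo)
        }
        data[[vcol]][i0:i1] <- visibility_threshold
        interpolated[i0:i1] <- TRUE
      }
    }
  }
  vis <- as.matrix(data[paste0(landmark_names(), "_v")])
  keep <- rowSums(vis < visibility_threshold) == 0L
  dropped <- sum(!keep)
  if (!any(keep)) {
    stop(sprintf(
      "all %d frames dropped (participant %s day %d block %d): no frame has all landmarks at visibility >= %g",
      n, series$participant_id, series$day, series$block,
      visibility_threshold), call. = FALSE)
  }
  landmark_series(series$participant_id, series$day, series$block,
                  series$fps, data[keep, ],
                  n_interpolated = series$n_interpolated +
                    sum(interpolated & keep),
                  n_dropped = series$n_dropped + dropped)
}

#' Read per-frame 33-keypoint pose records from JSON lines
#'
#' Each line holds one frame:
#' `{"frame": i, "landmarks": [{"x":..., "y":..., "visibility":...} x 33]}`,
#' with coordinates normalized to \[0, 1\] as emitted by full-body pose
#' estimators.
#'
#' @param path Path to a JSON-lines file.
#' @return A list of per-frame records suitable for [adapt_pose33()].
#' @export
read_pose33_jsonl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyDataFrame = TRUE))
}

#' Select the eight landmarks of interest from 33-keypoint pose output
#'
#' Adapts raw full-body pose-estimator output (33 keypoints per frame,
#' normalized coordinates) to a [landmark_series()] over the eight landmarks
#' used by the kinematic analyses. Hand-side keypoints (pinky, index, wrist,
#' elbow) are taken from the participant's paretic side; normalized
#' coordinates are converted to pixels by multiplying with the frame width
#' and height. Frames missing any required keypoint are flagged by setting
#' its visibility to 0 (so [preprocess()] handles them downstream).
#'
#' @param raw List of per-frame records as returned by [read_pose33_jsonl()]:
#'   each has `frame` and `landmarks`, a 33-row data frame (or list) with
#'   `x`, `y` in \[0, 1\] and `visibility`.
#' @param info One-row participant metadata (see [read_participants()]) with
#'   at least `participant_id` and `paretic_side`.
#' @param fps Sampling rate of the recording (Hz).
#' @param width,height Frame dimensions in pixels (both > 0).
#' @param day,block Session and block labels for the resulting series.
#' @return A [landmark_series()] in pixel coordinates.
#' @export
adapt_pose33 <- function(raw, info, fps, width, height, day = 1L, block = 1L) {
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0) {
    stop("frame `width` and `height` must be positive", call. = FALSE)
  }
  idx <- landmark_source_indices(info$paretic_side) + 1L # to 1-based
  frames <- vapply(raw, function(r) as.integer(r$frame), integer(1))
  ord <- order(frames)
  raw <- raw[ord]
  frames <- frames[ord]
  n <- length(raw)
  cols <- stats::setNames(
    rep(list(numeric(n)), length(landmark_cols())), landmark_cols())
  for (i in seq_len(n)) {
    lms <- raw[[i]]$landmarks
    if (is.data.frame(lms)) {
      get <- function(j) if (j <= nrow(lms))
        list(x = lms$x[j], y = lms$y[j], v = lms$visibility[j]) else NULL
    } else {
      get <- function(j) {
        if (j > length(lms) || is.null(lms[[j]])) return(NULL)
        list(x = lms[[j]]$x, y = lms[[j]]$y, v = lms[[j]]$visibility)
      }
    }
    for (lm in landmark_names()) {
      rec <- get(idx[[lm]])
      if (is.null(rec) || is.null(rec$x) || is.na(rec$x) || is.na(rec$y)) {
        # keypoint absent: keep a placeholder position, mark invisible
        cols[[paste0(lm, "_x")]][i] <- 0
        cols[[paste0(lm, "_y")]][i] <- 0
        cols[[paste0(lm, "_v")]][i] <- 0
      } else {
        cols[[paste0(lm, "_x")]][i] <- rec$x * width
        cols[[paste0(lm, "_y")]][i] <- rec$y * height
        cols[[paste0(lm, "_v")]][i] <- if (is.null(rec$v) || is.na(rec$v)) 1
          else rec$v
      }
    }
  }
  data <- tibble::as_tibble(c(list(frame = frames), cols))
  landmark_series(info$participant_id, day, block, fps, data)
}
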