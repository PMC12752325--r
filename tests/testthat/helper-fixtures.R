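# Build a landmark_series from per-landmark coordinate matrices.
# `coords` is a named list landmark -> n x 2 matrix; landmarks not named are
# held constant at `default_pos`. All visibilities default to 1.
make_series <- function(coords = list(), n = NULL, fps = 30,
                        participant_id = "P1", day = 1L, block = 1L,
                        default_pos = c(100, 100), visibility = NULL) {
  if (is.null(n)) {
    stopifnot(length(coords) > 0L)
    n <- nrow(coords[[1]])
  }
  cols <- list(frame = seq_len(n))
  for (lm in landmark_names()) {
    m <- coords[[lm]]
    if (is.null(m)) {
      m <- matrix(rep(default_pos, each = n), n, 2)
    }
    cols[[paste0(lm, "_x")]] <- m[, 1]
    cols[[paste0(lm, "_y")]] <- m[, 2]
    cols[[paste0(lm, "_v")]] <- if (is.null(visibility)) rep(1, n) else
      visibility[[lm]] %||% rep(1, n)
  }
  landmark_series(participant_id, day, block, fps, tibble::as_tibble(cols))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_track <- function(n, fps = 30, label = "palm", scale = 50) {
  point_track(label, stats::rnorm(n, 0, scale), stats::rnorm(n, 0, scale),
              fps)
}

# literal-formula oracles, written as naive element-wise loops so they stay
# independent of the vectorized implementation
bve_oracle <- function(x, y) {
  n <- length(x)
  xc <- sum(x) / n
  yc <- sum(y) / n
  total <- 0
  for (i in seq_len(n)) {
    total <- total + (x[i] - xc)^2 + (y[i] - yc)^2
  }
  sqrt(total / n)
}

speed_oracle <- function(x, y, fps) {
  out <- numeric(length(x) - 1L)
  for (f in 2:length(x)) {
    out[f - 1L] <- sqrt((x[f] - x[f - 1L])^2 + (y[f] - y[f - 1L])^2) /
      (1 / fps)
  }
  out
}

# minimal metadata table for synthetic participants
make_info <- function(ids, paretic = "R", fma = 50) {
  tibble::tibble(participant_id = ids,
                 age = 70, sex = "F", time_since_stroke_months = 12,
                 hemisphere = ifelse(rep(paretic, length(ids)) == "R",
                                     "L", "R"),
                 fma_ue = rep_len(fma, length(ids)),
                 paretic_side = rep_len(paretic, length(ids)))
}

# block-summary rows with chosen outcome values (other fields filled in)
make_summary <- function(participant_id, day, block, value = 1,
                         bve_palm = value, bve_shoulder = value,
                         bve_trunk = value, mean_speed_palm = value) {
  tibble::tibble(participant_id = participant_id, day = as.integer(day),
                 block = as.integer(block),
                 bve_palm = bve_palm, bve_shoulder = bve_shoulder,
                 bve_trunk = bve_trunk, mean_speed_palm = mean_speed_palm,
                 mean_speed_shoulder = mean_speed_palm / 4,
                 mean_speed_trunk = mean_speed_palm / 8,
                 n_frames = 100L, n_interpolated = 0L, n_dropped = 0L)
}
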