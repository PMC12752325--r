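#' Trajectory panels for palm, shoulder and trunk
#'
#' Plots the raw effector trajectories of each block, faceted by (day,
#' block), with the participant's initial trunk outline (shoulders and hips
#' at the first frame) drawn as a polygon. The y axis is reversed so that
#' "up" in the image is up on the page (storage uses image convention,
#' origin top-left).
#'
#' @param series_list List of preprocessed [landmark_series()] for one
#'   participant.
#' @param info Participant metadata tibble (paretic side resolution).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(series_list, info) {
  if (inherits(series_list, "landmark_series")) series_list <- list(series_list)
  stopifnot(length(series_list) > 0L)
  pid <- unique(vapply(series_list, function(s) s$participant_id, character(1)))
  if (length(pid) != 1L) {
    stop("plot_trajectories expects blocks from a single participant",
         call. = FALSE)
  }
  row <- info[info$participant_id == pid, , drop = FALSE]
  if (nrow(row) != 1L) stop("no metadata row for participant ", pid,
                            call. = FALSE)
  tracks <- dplyr::bind_rows(lapply(series_list, function(s) {
    lab <- sprintf("Day %d / Block %d", s$day, s$block)
    mk <- function(tr) tibble::tibble(cell = lab, effector = tr$label,
                                      x = tr$x, y = tr$y)
    dplyr::bind_rows(mk(palm_track(s)),
                     mk(shoulder_track(s, row$paretic_side)),
                     mk(trunk_track(s)))
  }))
  outline <- dplyr::bind_rows(lapply(series_list, function(s) {
    d1 <- s$data[1, ]
    lms <- c("shoulder_left", "shoulder_right", "hip_right", "hip_left")
    tibble::tibble(cell = sprintf("Day %d / Block %d", s$day, s$block),
                   x = vapply(lms, function(l) d1[[paste0(l, "_x")]],
                              numeric(1)),
                   y = vapply(lms, function(l) d1[[paste0(l, "_y")]],
                              numeric(1)))
  }))
  ggplot2::ggplot(tracks, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(data = outline, fill = "black", alpha = 0.6) +
    ggplot2::geom_path(ggplot2::aes(colour = .data$effector), alpha = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~cell) +
    ggplot2::labs(title = paste("Participant", pid),
                  x = "x (px)", y = "y (px)", colour = "effector") +
    ggplot2::theme_minimal()
}

#' BVE bar charts over the analysis grid
#'
#' One panel per participant, bars for palm, shoulder and trunk BVE in each
#' (day, block) cell of the analysis grid.
#'
#' @param summaries Tibble of block summaries ([summarize_block()] rows).
#' @param days,blocks Analysis grid.
#' @return A ggplot object.
#' @export
plot_bve_bars <- function(summaries, days = c(1L, 5L), blocks = c(1L, 5L)) {
  sel <- summaries[summaries$day %in% days & summaries$block %in% blocks, ]
  long <- tidyr::pivot_longer(
    sel[c("participant_id", "day", "block",
          "bve_palm", "bve_shoulder", "bve_trunk")],
    cols = dplyr::starts_with("bve_"),
    names_to = "effector", values_to = "bve")
  long$effector <- sub("^bve_", "", long$effector)
  long$cell <- sprintf("D%d B%d", long$day, long$block)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cell, y = .data$bve,
                                     fill = .data$effector)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~participant_id) +
    ggplot2::labs(x = NULL, y = "BVE (px)", fill = "effector") +
    ggplot2::theme_minimal()
}

#' Change-quadrant scatter of hand outcomes vs proximal BVE
#'
#' Plots the per-participant change (last minus first block of practice) in
#' each hand outcome (palm BVE, mean palm speed) against the change in trunk
#' and shoulder BVE, one panel per pairing, with dashed zero lines marking
#' the quadrants. Points are shaded by FMA-UE (darker = lower score, i.e.
#' greater impairment).
#'
#' @param changes Tibble from [change_scores()].
#' @return A ggplot object, or `NULL` (with a warning) if `changes` is empty.
#' @export
plot_change_quadrant <- function(changes) {
  if (nrow(changes) == 0L) {
    warning("no change scores to plot", call. = FALSE)
    return(NULL)
  }
  long <- tidyr::pivot_longer(
    changes,
    cols = c("delta_bve_trunk", "delta_bve_shoulder"),
    names_to = "proximal", values_to = "delta_proximal")
  long <- tidyr::pivot_longer(
    long, cols = c("delta_bve_palm", "delta_mean_speed_palm"),
    names_to = "hand", values_to = "delta_hand")
  long$proximal <- sub("^delta_bve_", "", long$proximal)
  long$hand <- c(delta_bve_palm = "palm BVE",
                 delta_mean_speed_palm = "mean palm speed")[long$hand]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$delta_proximal,
                                     y = .data$delta_hand,
                                     fill = .data$fma_ue)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_point(shape = 21, size = 3, colour = "grey30") +
    ggplot2::scale_fill_gradient(low = "grey10", high = "grey90",
                                 limits = c(0, 66)) +
    ggplot2::facet_grid(hand ~ proximal, scales = "free") +
    ggplot2::labs(x = "change in proximal BVE (px)",
                  y = "change in hand outcome",
                  fill = "FMA-UE") +
    ggplot2::theme_minimal()
}
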