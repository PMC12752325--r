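#' Simulate a cohort and write it to disk
#'
#' Runs [simulate_cohort()] and writes the landmark CSV, the participant
#' metadata CSV, and a ground-truth JSON into `out_dir`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(config)
  paths <- c(landmarks = file.path(out_dir, "landmarks.csv"),
             participants = file.path(out_dir, "participants.csv"),
             truth = file.path(out_dir, "ground_truth.json"))
  write_landmark_csv(sim$series, paths[["landmarks"]])
  utils::write.csv(
    sim$participants[c("participant_id", "age", "sex",
                       "time_since_stroke_months", "hemisphere", "fma_ue")],
    paths[["participants"]], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(participants = sim$truth$participants,
         blocks = sim$truth$blocks,
         config = unclass(sim$truth$config)),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Ingest, preprocess and summarize a recorded cohort
#'
#' Reads a landmark CSV and participant metadata, preprocesses every block
#' ([preprocess()]), computes block summaries, the group mean/SD table over
#' the analysis grid, and per-participant change scores, and writes all
#' three as CSV.
#'
#' @param landmarks_csv,participants_csv Input files in the package dialects.
#' @param out_dir Output directory (created if needed).
#' @param days,blocks Analysis grid (default first and last of 1..5).
#' @param visibility_threshold,max_gap Passed to [preprocess()].
#' @return List with `summaries`, `group_table`, `changes` tibbles and the
#'   written `paths`, invisibly.
#' @export
run_summarize <- function(landmarks_csv, participants_csv, out_dir,
                          days = c(1L, 5L), blocks = c(1L, 5L),
                          visibility_threshold = 0.5, max_gap = 5L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  participants <- read_participants(participants_csv)
  series <- read_landmark_csv(landmarks_csv)
  series <- lapply(series, preprocess,
                   visibility_threshold = visibility_threshold,
                   max_gap = max_gap)
  summaries <- summarize_cohort(series, participants)
  gt <- group_table(summaries, days = days, blocks = blocks)
  changes <- change_scores(summaries, participants,
                           first = c(days[1], blocks[1]),
                           last = c(days[length(days)],
                                    blocks[length(blocks)]))
  paths <- c(summaries = file.path(out_dir, "block_summaries.csv"),
             group_table = file.path(out_dir, "group_table.csv"),
             changes = file.path(out_dir, "change_scores.csv"))
  utils::write.csv(summaries, paths[["summaries"]], row.names = FALSE)
  utils::write.csv(gt, paths[["group_table"]], row.names = FALSE)
  utils::write.csv(changes, paths[["changes"]], row.names = FALSE)
  invisible(list(summaries = summaries, group_table = gt, changes = changes,
                 paths = paths))
}

#' Fit the two group models and write their reports
#'
#' Builds the long analysis table over the analysis grid and fits the two
#' linear mixed-effects models (palm BVE; mean palm speed), writing a text
#' and a JSON report for each.
#'
#' @param summaries_csv Block-summary CSV written by [run_summarize()].
#' @param participants_csv Participant metadata CSV.
#' @param out_dir Output directory (created if needed).
#' @param days,blocks Analysis grid.
#' @param center_covariates Passed to [fit_lme()].
#' @return List with the two `lme_fit` objects and the written `paths`,
#'   invisibly.
#' @export
run_model <- function(summaries_csv, participants_csv, out_dir,
                      days = c(1L, 5L), blocks = c(1L, 5L),
                      center_covariates = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summaries <- tibble::as_tibble(
    utils::read.csv(summaries_csv, stringsAsFactors = FALSE))
  summaries$participant_id <- as.character(summaries$participant_id)
  participants <- read_participants(participants_csv)
  tab <- build_model_table(summaries, participants,
                           days = days, blocks = blocks)
  fits <- list()
  paths <- character()
  for (outcome in c("bve_palm", "mean_speed_palm")) {
    fit <- fit_lme(tab, outcome, center_covariates = center_covariates)
    fits[[outcome]] <- fit
    txt <- file.path(out_dir, paste0("model_", outcome, ".txt"))
    jsn <- file.path(out_dir, paste0("model_", outcome, ".json"))
    writeLines(report(fit, "text"), txt)
    writeLines(report(fit, "json"), jsn)
    paths <- c(paths, txt, jsn)
  }
  invisible(list(fits = fits, paths = paths))
}

#' Render the pipeline figures
#'
#' Writes per-participant trajectory panels, the BVE bar chart, and the
#' change-quadrant scatter as PNG files.
#'
#' @param landmarks_csv,participants_csv Input files.
#' @param out_dir Output directory (created if needed).
#' @param days,blocks Analysis grid.
#' @param visibility_threshold,max_gap Passed to [preprocess()].
#' @param width,height,dpi Device parameters for [ggplot2::ggsave()].
#' @return Character vector of written figure paths, invisibly.
#' @export
run_plot <- function(landmarks_csv, participants_csv, out_dir,
                     days = c(1L, 5L), blocks = c(1L, 5L),
                     visibility_threshold = 0.5, max_gap = 5L,
                     width = 8, height = 6, dpi = 150) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  participants <- read_participants(participants_csv)
  series <- read_landmark_csv(landmarks_csv)
  series <- lapply(series, preprocess,
                   visibility_threshold = visibility_threshold,
                   max_gap = max_gap)
  keep <- vapply(series, function(s) s$day %in% days && s$block %in% blocks,
                 logical(1))
  series <- series[keep]
  summaries <- summarize_cohort(series, participants)
  changes <- change_scores(summaries, participants,
                           first = c(days[1], blocks[1]),
                           last = c(days[length(days)],
                                    blocks[length(blocks)]))
  paths <- character()
  by_pid <- split(series,
                  vapply(series, function(s) s$participant_id, character(1)))
  for (pid in names(by_pid)) {
    p <- plot_trajectories(by_pid[[pid]], participants)
    f <- file.path(out_dir, paste0("trajectories_", pid, ".png"))
    ggplot2::ggsave(f, p, width = width, height = height, dpi = dpi)
    paths <- c(paths, f)
  }
  f <- file.path(out_dir, "bve_bars.png")
  ggplot2::ggsave(f, plot_bve_bars(summaries, days, blocks),
                  width = width, height = height, dpi = dpi)
  paths <- c(paths, f)
  quad <- plot_change_quadrant(changes)
  if (!is.null(quad)) {
    f <- file.path(out_dir, "change_quadrant.png")
    ggplot2::ggsave(f, quad, width = width, height = height, dpi = dpi)
    paths <- c(paths, f)
  }
  invisible(paths)
}
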