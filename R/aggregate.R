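#' Per-block kinematic summary
#'
#' Computes the block-level kinematic outcomes for one recording: BVE of the
#' palm, paretic shoulder and trunk effectors, and mean speed of each (only
#' palm speed enters the group models, but all three are stored). The paretic
#' side is resolved from the participant metadata. Preprocessing counts are
#' carried through.
#'
#' @param series A preprocessed [landmark_series()].
#' @param info Participant metadata tibble (see [read_participants()]); the
#'   row matching `series$participant_id` is used.
#' @return A one-row tibble: `participant_id`, `day`, `block`, `bve_palm`,
#'   `bve_shoulder`, `bve_trunk`, `mean_speed_palm`, `mean_speed_shoulder`,
#'   `mean_speed_trunk`, `n_frames`, `n_interpolated`, `n_dropped`.
#' @export
summarize_block <- function(series, info) {
  stopifnot(inherits(series, "landmark_series"))
  row <- info[info$participant_id == series$participant_id, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("no (unique) metadata row for participant ", series$participant_id,
         call. = FALSE)
  }
  ctx <- sprintf("participant %s day %d block %d",
                 series$participant_id, series$day, series$block)
  withCallingHandlers(
    {
      palm <- palm_track(series)
      shoulder <- shoulder_track(series, row$paretic_side)
      trunk <- trunk_track(series)
      tibble::tibble(
        participant_id = series$participant_id,
        day = series$day, block = series$block,
        bve_palm = bve(palm),
        bve_shoulder = bve(shoulder),
        bve_trunk = bve(trunk),
        mean_speed_palm = mean_speed(palm),
        mean_speed_shoulder = mean_speed(shoulder),
        mean_speed_trunk = mean_speed(trunk),
        n_frames = nrow(series$data),
        n_interpolated = series$n_interpolated,
        n_dropped = series$n_dropped
      )
    },
    error = function(e) {
      stop(ctx, ": ", conditionMessage(e), call. = FALSE)
    }
  )
}

#' Summarize every block of a cohort
#'
#' @param series_list List of preprocessed [landmark_series()].
#' @param participants Participant metadata tibble.
#' @return Tibble of [summarize_block()] rows, one per series.
#' @export
summarize_cohort <- function(series_list, participants) {
  dplyr::bind_rows(lapply(series_list, summarize_block, info = participants))
}

block_outcomes <- function() {
  c("bve_palm", "bve_shoulder", "bve_trunk", "mean_speed_palm")
}

#' Group mean/SD table over the analysis grid
#'
#' For each kinematic outcome and each (day, block) cell of the analysis
#' grid, computes the across-participant mean and sample SD (n-1 denominator;
#' `NA` when a cell holds a single participant). Cells are ordered day-major.
#' The default grid is the first and last block of the first and last
#' session.
#'
#' @param summaries Tibble of block summaries ([summarize_block()] rows).
#' @param days,blocks Integer vectors defining the analysis grid.
#' @return Tibble with columns `outcome`, `day`, `block`, `mean`, `sd`, `n`.
#' @export
group_table <- function(summaries, days = c(1L, 5L), blocks = c(1L, 5L)) {
  sel <- summaries[summaries$day %in% days & summaries$block %in% blocks, ]
  dup <- duplicated(sel[c("participant_id", "day", "block")])
  if (any(dup)) {
    d <- sel[dup, ][1, ]
    stop(sprintf("duplicate summary for participant %s day %d block %d",
                 d$participant_id, d$day, d$block), call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    sel[c("participant_id", "day", "block", block_outcomes())],
    cols = dplyr::all_of(block_outcomes()),
    names_to = "outcome", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$outcome, .data$day, .data$block),
    mean = mean(.data$value),
    sd = if (dplyr::n() >= 2L) stats::sd(.data$value) else NA_real_,
    n = dplyr::n(),
    .groups = "drop")
  out$outcome <- factor(out$outcome, levels = block_outcomes())
  out <- out[order(out$outcome, out$day, out$block), ]
  out$outcome <- as.character(out$outcome)
  out
}

#' Change scores across practice
#'
#' Per-participant change in each kinematic outcome, computed as the value
#' in the last block minus the value in the first block of practice (default:
#' day 5 block 5 minus day 1 block 1), joined with the participant's FMA-UE
#' score. Participants missing either endpoint block are reported in the
#' `skipped` attribute (and a warning), never silently dropped.
#'
#' @param summaries Tibble of block summaries.
#' @param participants Participant metadata tibble (for `fma_ue`).
#' @param first,last Length-2 vectors `c(day, block)` naming the endpoint
#'   blocks.
#' @return Tibble with one row per participant holding `delta_bve_palm`,
#'   `delta_bve_shoulder`, `delta_bve_trunk`, `delta_mean_speed_palm` and
#'   `fma_ue`; attribute `skipped` lists participants lacking an endpoint.
#' @export
change_scores <- function(summaries, participants,
                          first = c(1L, 1L), last = c(5L, 5L)) {
  stopifnot(length(first) == 2L, length(last) == 2L)
  pick <- function(ep) {
    summaries[summaries$day == ep[1] & summaries$block == ep[2], ]
  }
  a <- pick(first)
  b <- pick(last)
  ids <- unique(summaries$participant_id)
  have_both <- ids[ids %in% a$participant_id & ids %in% b$participant_id]
  skipped <- setdiff(ids, have_both)
  if (length(skipped) > 0L) {
    warning("participants missing an endpoint block, skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::inner_join(
    a[c("participant_id", block_outcomes())],
    b[c("participant_id", block_outcomes())],
    by = "participant_id", suffix = c("_first", "_last"))
  out <- tibble::tibble(
    participant_id = joined$participant_id,
    delta_bve_palm = joined$bve_palm_last - joined$bve_palm_first,
    delta_bve_shoulder = joined$bve_shoulder_last - joined$bve_shoulder_first,
    delta_bve_trunk = joined$bve_trunk_last - joined$bve_trunk_first,
    delta_mean_speed_palm =
      joined$mean_speed_palm_last - joined$mean_speed_palm_first)
  out <- dplyr::left_join(out, participants[c("participant_id", "fma_ue")],
                          by = "participant_id")
  attr(out, "skipped") <- skipped
  out
}
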