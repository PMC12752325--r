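#' Read participant metadata
#'
#' Reads the participant metadata CSV dialect: header
#' `participant_id,age,sex,time_since_stroke_months,hemisphere,fma_ue`.
#' `hemisphere` is the hemisphere of stroke (`L`/`R`); the paretic side is
#' derived as the contralateral side. `fma_ue` is the upper-extremity
#' Fugl-Meyer score (0-66, higher = less impaired).
#'
#' @param path Path to the metadata CSV.
#' @return A tibble with one row per participant and an added `paretic_side`
#'   column.
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # "F" alone would otherwise be parsed as logical FALSE
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character",
                                       sex = "character",
                                       hemisphere = "character"))
  required <- c("participant_id", "age", "sex", "time_since_stroke_months",
                "hemisphere", "fma_ue")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("participant CSV is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_participants(tibble::as_tibble(df))
}

validate_participants <- function(df) {
  if (!all(df$sex %in% c("F", "M"))) {
    stop("`sex` must be 'F' or 'M'", call. = FALSE)
  }
  if (!all(df$hemisphere %in% c("L", "R"))) {
    stop("`hemisphere` must be 'L' or 'R'", call. = FALSE)
  }
  if (any(df$fma_ue < 0 | df$fma_ue > 66)) {
    stop("`fma_ue` must lie in [0, 66]", call. = FALSE)
  }
  if (anyDuplicated(df$participant_id)) {
    stop("duplicate participant_id in metadata", call. = FALSE)
  }
  df$participant_id <- as.character(df$participant_id)
  df$paretic_side <- ifelse(df$hemisphere == "L", "R", "L")
  df
}

#' Example seven-participant stroke cohort
#'
#' Metadata for an example cohort of seven sub-acute and chronic stroke
#' survivors (ages 67-79, FMA-UE 40-66) used throughout the documentation
#' and tests. The paretic side is contralateral to the hemisphere of stroke.
#'
#' @return A tibble with columns `participant_id`, `age`, `sex`,
#'   `time_since_stroke_months`, `hemisphere`, `fma_ue`, `paretic_side`.
#' @export
#' @examples
#' example_participants()
example_participants <- function() {
  read_participants(system.file("extdata", "participants.csv",
                                package = "reachkin", mustWork = TRUE))
}
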