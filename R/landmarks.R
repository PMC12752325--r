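#' The eight tracked landmarks
#'
#' Kinematic analyses in this package use eight body landmarks: the pinky
#' finger, index finger, wrist, and elbow of the paretic hand, plus both
#' shoulders and both hips. Hand-side landmarks are stored under side-neutral
#' names (`pinky`, `index`, ...); which source-side keypoint they came from is
#' resolved at ingest from the participant's paretic side (see
#' [adapt_pose33()]).
#'
#' @return Character vector of the eight landmark names, in canonical order.
#' @export
#' @examples
#' landmark_names()
landmark_names <- function() {
  c("pinky", "index", "wrist", "elbow",
    "shoulder_left", "shoulder_right", "hip_left", "hip_right")
}

# 0-based keypoint indices of the 33-landmark full-body pose convention
# (BlazePose ordering): 11/12 shoulders, 13/14 elbows, 15/16 wrists,
# 17/18 pinkies, 19/20 index fingers, 23/24 hips (left/right).
pose33_left <- c(pinky = 17L, index = 19L, wrist = 15L, elbow = 13L)
pose33_right <- c(pinky = 18L, index = 20L, wrist = 16L, elbow = 14L)

#' Source indices of the eight landmarks in the 33-keypoint pose convention
#'
#' Maps each of the eight tracked landmark names to its 0-based index in the
#' 33-keypoint full-body pose output. The four hand/arm landmarks are taken
#' from the paretic side; shoulders and hips are always both included.
#'
#' @param paretic_side `"L"` or `"R"`: the participant's paretic side.
#' @return Named integer vector (names as in [landmark_names()]) of 0-based
#'   source indices. All eight indices are distinct.
#' @export
#' @examples
#' landmark_source_indices("L")
landmark_source_indices <- function(paretic_side) {
  paretic_side <- match.arg(paretic_side, c("L", "R"))
  hand <- if (paretic_side == "L") pose33_left else pose33_right
  out <- c(hand,
           shoulder_left = 11L, shoulder_right = 12L,
           hip_left = 23L, hip_right = 24L)
  stopifnot(!anyDuplicated(out))
  out
}
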