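#' @include AllClasses.R AllGenerics.R
NULL

#' Per-frame resident-head to intruder-body distance
#'
#' @param session a [PoseSession-class].
#' @return numeric vector of Euclidean distances (pixels); `NA` on invalid
#'   frames.
#' @export
setMethod("headBodyDistance", "PoseSession", function(session) {
  d <- sqrt(rowSums((session@residentHeadXy - session@intruderBodyXy)^2))
  d[!session@validFrames] <- NA_real_
  d
})

#' Per-frame approach angle of the resident toward the intruder
#'
#' Angle between the resident's heading vector (body centroid to head) and
#' the vector from the resident's head to the intruder's body, in degrees.
#' 0 deg means the intruder is directly ahead, 180 deg directly behind.
#'
#' @param session a [PoseSession-class].
#' @return numeric vector of angles in `[0, 180]` degrees; `NA` on invalid
#'   frames and on frames with a degenerate heading (head coincident with
#'   body).
#' @export
setMethod("approachAngle", "PoseSession", function(session) {
  h <- session@residentHeadXy - session@residentBodyXy      # heading
  v <- session@intruderBodyXy - session@residentHeadXy      # head -> intruder
  nh <- sqrt(rowSums(h^2))
  nv <- sqrt(rowSums(v^2))
  cosA <- rowSums(h * v) / (nh * nv)
  cosA <- pmin(1, pmax(-1, cosA))
  ang <- acos(cosA) * 180 / pi
  ang[!session@validFrames | nh < .Machine$double.eps |
        nv < .Machine$double.eps] <- NA_real_
  ang
})

#' Detect social-interaction intervals from pose geometry
#'
#' A frame counts as interacting iff the resident-head to intruder-body
#' distance is at most `distThreshPx` AND the approach angle is at most
#' `angleThreshDeg` (inclusive comparisons). Gaps shorter than `mergeGapS`
#' are then bridged and runs shorter than `minDurS` dropped. Frames with
#' missing geometry never count as interacting, so tracking dropouts break
#' runs unless bridged by `mergeGapS`.
#'
#' @param distance per-frame distances from [headBodyDistance()].
#' @param angle per-frame angles from [approachAngle()], same length.
#' @param fps frame rate (frames/s) used to convert frames to seconds.
#' @param distThreshPx distance threshold in pixels (default 60).
#' @param angleThreshDeg angle threshold in degrees (default 135).
#' @param minDurS minimum interval duration (s, default 0.5); applied after
#'   merging.
#' @param mergeGapS maximum gap to bridge (s, default 0.2).
#' @return An [EventSeries-class] labelled `"interaction"`.
#' @export
detectInteraction <- function(distance, angle, fps, distThreshPx = 60,
                              angleThreshDeg = 135, minDurS = 0.5,
                              mergeGapS = 0.2) {
  if (length(distance) != length(angle))
    stop("distance and angle must be per-frame aligned")
  if (distThreshPx < 0 || angleThreshDeg < 0 || minDurS < 0 || mergeGapS < 0)
    stop("thresholds must be non-negative")
  mask <- !is.na(distance) & !is.na(angle) &
    distance <= distThreshPx & angle <= angleThreshDeg
  iv <- maskToIntervals(mask, fps)
  iv <- postprocessIntervals(iv, minDurS = minDurS, mergeGapS = mergeGapS)
  EventSeries(iv, label = "interaction")
}

#' Per-frame interaction rule (no post-processing)
#'
#' The raw boolean frame rule behind [detectInteraction()], exposed for
#' auditing: `distance <= distThreshPx & angle <= angleThreshDeg`, with
#' missing frames FALSE.
#'
#' @inheritParams detectInteraction
#' @return logical vector per frame.
#' @export
interactionFrameMask <- function(distance, angle, distThreshPx = 60,
                                 angleThreshDeg = 135) {
  !is.na(distance) & !is.na(angle) &
    distance <= distThreshPx & angle <= angleThreshDeg
}

#' Total interaction time of an event series
#'
#' @param series an [EventSeries-class].
#' @return Sum of interval durations in seconds (0 for an empty series).
#' @export
setMethod("interactionTime", "EventSeries", function(series) {
  iv <- series@intervals
  if (!nrow(iv)) return(0)
  sum(iv$endS - iv$startS)
})
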