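#' @import methods
NULL

# ---------------------------------------------------------------------------
# Core S4 containers.  Tabular derived results (rank tables, bout tables,
# response labels, overlap tables) are returned as plain data.frames.
# ---------------------------------------------------------------------------

#' TournamentRecord: pairwise tube-test outcomes for one cage
#'
#' Holds the trial list of a round-robin tube dominance tournament: on each
#' of several test days every ordered pair of cage mates meets at least once
#' and exactly one mouse wins each trial.
#'
#' @slot trials data.frame with columns `day` (integer), `mouseA`, `mouseB`,
#'   `winner` (character ids); `winner` is always one of the two contestants.
#'
#' @examples
#' rec <- TournamentRecord(data.frame(
#'   day = 1L, mouseA = "m1", mouseB = "m2", winner = "m1"))
#' percentWins(rec, "m1")
#' @export
setClass("TournamentRecord", representation(trials = "data.frame"))

setValidity("TournamentRecord", function(object) {
  tr <- object@trials
  need <- c("day", "mouseA", "mouseB", "winner")
  if (!all(need %in% names(tr)))
    return(paste("trials must have columns", paste(need, collapse = ", ")))
  if (nrow(tr) > 0) {
    if (any(tr$winner != tr$mouseA & tr$winner != tr$mouseB))
      return("winner must be one of the two contestants in every trial")
    if (any(tr$mouseA == tr$mouseB))
      return("a mouse cannot compete against itself")
    if (any(!is.finite(tr$day) | tr$day < 1))
      return("day must be a positive integer")
  }
  TRUE
})

#' @rdname TournamentRecord-class
#' @param trials data.frame of trials (day, mouseA, mouseB, winner).
#' @return A `TournamentRecord` object.
#' @export
TournamentRecord <- function(trials) {
  trials$day <- as.integer(trials$day)
  for (col in c("mouseA", "mouseB", "winner"))
    trials[[col]] <- as.character(trials[[col]])
  new("TournamentRecord", trials = trials)
}

setMethod("show", "TournamentRecord", function(object) {
  tr <- object@trials
  mice <- sort(unique(c(tr$mouseA, tr$mouseB)))
  cat("TournamentRecord:", nrow(tr), "trials,", length(mice), "mice,",
      length(unique(tr$day)), "days\n")
})

#' Trial list of a tournament
#' @param object a `TournamentRecord`.
#' @return data.frame of trials.
#' @export
tournamentTrials <- function(object) object@trials

#' LickStream: timestamped licks on one spout in one session
#'
#' @slot spout one of `"alcohol"`, `"water"`, `"sucrose"`.
#' @slot lickTimesS strictly increasing, non-negative lick times (s).
#' @slot mouse mouse id.
#' @slot condition `"pre_SI"` (group housed) or `"SI"` (social isolation),
#'   or `NA` when not applicable.
#' @slot meta free-form metadata list (e.g. trial labels, stimulation flag).
#' @export
setClass("LickStream", representation(
  spout = "character", lickTimesS = "numeric",
  mouse = "character", condition = "character", meta = "list"))

setValidity("LickStream", function(object) {
  if (!object@spout %in% c("alcohol", "water", "sucrose"))
    return("spout must be one of alcohol, water, sucrose")
  t <- object@lickTimesS
  if (length(t)) {
    if (any(!is.finite(t)) || any(t < 0)) return("lick times must be finite and non-negative")
    if (any(diff(t) <= 0)) return("lick times must be strictly increasing")
  }
  if (!object@condition %in% c("pre_SI", "SI", NA_character_))
    return("condition must be pre_SI, SI or NA")
  TRUE
})

#' @rdname LickStream-class
#' @param lickTimesS numeric vector of lick times in seconds.
#' @param spout spout label.
#' @param mouse mouse id.
#' @param condition housing condition label.
#' @param meta metadata list.
#' @return A `LickStream`.
#' @export
LickStream <- function(lickTimesS, spout = "alcohol", mouse = NA_character_,
                       condition = NA_character_, meta = list()) {
  new("LickStream", spout = spout, lickTimesS = as.numeric(lickTimesS),
      mouse = as.character(mouse), condition = as.character(condition),
      meta = meta)
}

setMethod("show", "LickStream", function(object) {
  cat(sprintf("LickStream: %d licks on %s spout (mouse %s, condition %s)\n",
              length(object@lickTimesS), object@spout, object@mouse,
              object@condition))
})

#' Lick times of a stream
#' @param object a `LickStream`.
#' @return numeric vector of lick times (s).
#' @export
lickTimes <- function(object) object@lickTimesS

#' PoseSession: two-animal keypoint tracks
#'
#' Per-frame pixel coordinates of the resident's head and body centroid and
#' the intruder's body centroid, as exported by pose-estimation software.
#'
#' @slot fps frames per second.
#' @slot residentHeadXy,residentBodyXy,intruderBodyXy n x 2 numeric matrices.
#' @slot validFrames logical mask; coordinates must be finite where TRUE.
#' @export
setClass("PoseSession", representation(
  fps = "numeric", residentHeadXy = "matrix", residentBodyXy = "matrix",
  intruderBodyXy = "matrix", validFrames = "logical"))

setValidity("PoseSession", function(object) {
  n <- nrow(object@residentHeadXy)
  mats <- list(object@residentHeadXy, object@residentBodyXy, object@intruderBodyXy)
  if (any(vapply(mats, ncol, 0L) != 2L)) return("keypoint matrices must have 2 columns")
  if (any(vapply(mats, nrow, 0L) != n) || length(object@validFrames) != n)
    return("keypoint tracks and valid-frame mask must have equal length")
  if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
    return("fps must be a positive scalar")
  ok <- object@validFrames
  if (any(ok) && any(!vapply(mats, function(m) all(is.finite(m[ok, ])), TRUE)))
    return("coordinates must be finite on valid frames")
  TRUE
})

#' @rdname PoseSession-class
#' @param fps frame rate (frames/s).
#' @param residentHeadXy,residentBodyXy,intruderBodyXy n x 2 coordinate
#'   matrices (pixels).
#' @param validFrames logical mask of tracked frames (default all TRUE).
#' @return A `PoseSession`.
#' @export
PoseSession <- function(fps, residentHeadXy, residentBodyXy, intruderBodyXy,
                        validFrames = NULL) {
  toM <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  }
  residentHeadXy <- toM(residentHeadXy)
  if (is.null(validFrames)) validFrames <- rep(TRUE, nrow(residentHeadXy))
  new("PoseSession", fps = as.numeric(fps), residentHeadXy = residentHeadXy,
      residentBodyXy = toM(residentBodyXy), intruderBodyXy = toM(intruderBodyXy),
      validFrames = as.logical(validFrames))
}

setMethod("show", "PoseSession", function(object) {
  cat(sprintf("PoseSession: %d frames at %g fps (%.1f s), %d valid\n",
              nrow(object@residentHeadXy), object@fps,
              nrow(object@residentHeadXy) / object@fps,
              sum(object@validFrames)))
})

#' Number of frames in a pose session
#' @param object a `PoseSession`.
#' @return integer frame count.
#' @export
nFrames <- function(object) nrow(object@residentHeadXy)

#' EventSeries: labelled non-overlapping time intervals
#'
#' @slot intervals data.frame with columns `startS`, `endS`; sorted,
#'   non-overlapping, positive durations.
#' @slot label series label (e.g. `"interaction"`, `"stimulation"`).
#' @export
setClass("EventSeries", representation(intervals = "data.frame", label = "character"))

setValidity("EventSeries", function(object) {
  iv <- object@intervals
  if (!all(c("startS", "endS") %in% names(iv)))
    return("intervals must have columns startS, endS")
  if (nrow(iv)) {
    if (any(iv$endS <= iv$startS)) return("interval durations must be positive")
    if (nrow(iv) > 1 && any(iv$startS[-1] < iv$endS[-nrow(iv)]))
      return("intervals must be sorted and non-overlapping")
  }
  TRUE
})

#' @rdname EventSeries-class
#' @param intervals data.frame with `startS`, `endS` columns.
#' @param label series label.
#' @return An `EventSeries`.
#' @export
EventSeries <- function(intervals = data.frame(startS = numeric(0), endS = numeric(0)),
                        label = "interaction") {
  rownames(intervals) <- NULL
  new("EventSeries", intervals = intervals[, c("startS", "endS")], label = label)
}

setMethod("show", "EventSeries", function(object) {
  cat(sprintf("EventSeries '%s': %d intervals, %.2f s total\n", object@label,
              nrow(object@intervals), interactionTime(object)))
})

#' Intervals of an event series
#' @param object an `EventSeries`.
#' @return data.frame with `startS`, `endS`.
#' @export
eventIntervals <- function(object) object@intervals

#' PeriEventTensor: neurons x trials x time-bin activity around events
#'
#' Activity excerpted around event times and binned on a fixed peri-event
#' time base spanning the baseline window through the response window.
#' Values are raw trace units after [alignEvents()] and baseline-normalized
#' Z units after [zscoreBaseline()].
#'
#' @slot values numeric array `[neurons, trials, bins]`.
#' @slot binEdges bin edges relative to the event (s), length bins + 1.
#' @slot eventClass event class label (e.g. `"alcohol"`).
#' @slot neuronIds unique neuron ids.
#' @slot baselineWindow,responseWindow two-element windows (s) relative to
#'   the event; the baseline ends at or before the response starts.
#' @slot zScored logical; TRUE after baseline Z-normalization.
#' @export
setClass("PeriEventTensor", representation(
  values = "array", binEdges = "numeric", eventClass = "character",
  neuronIds = "character", baselineWindow = "numeric",
  responseWindow = "numeric", zScored = "logical"))

setValidity("PeriEventTensor", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a 3-d array [neurons, trials, bins]")
  if (length(object@binEdges) != d[3] + 1L)
    return("binEdges must have length nBins + 1")
  if (any(diff(object@binEdges) <= 0)) return("binEdges must increase")
  if (length(object@neuronIds) != d[1]) return("neuronIds must match dim 1")
  if (anyDuplicated(object@neuronIds)) return("neuron ids must be unique")
  bw <- object@baselineWindow; rw <- object@responseWindow
  if (length(bw) != 2L || length(rw) != 2L || bw[1] >= bw[2] || rw[1] >= rw[2])
    return("windows must be increasing two-element vectors")
  if (bw[2] > rw[1]) return("baseline window must precede the response window")
  TRUE
})

#' @rdname PeriEventTensor-class
#' @param values neurons x trials x bins array.
#' @param binEdges numeric vector of bin edges relative to event (s).
#' @param eventClass event class label.
#' @param neuronIds character vector of neuron ids.
#' @param baselineWindow,responseWindow two-element numeric windows (s).
#' @param zScored logical.
#' @return A `PeriEventTensor`.
#' @export
PeriEventTensor <- function(values, binEdges, eventClass = "event",
                            neuronIds = NULL, baselineWindow = c(-5, 0),
                            responseWindow = c(0, 5), zScored = FALSE) {
  if (is.null(neuronIds)) neuronIds <- paste0("n", seq_len(dim(values)[1]))
  new("PeriEventTensor", values = values, binEdges = as.numeric(binEdges),
      eventClass = eventClass, neuronIds = as.character(neuronIds),
      baselineWindow = as.numeric(baselineWindow),
      responseWindow = as.numeric(responseWindow), zScored = zScored)
}

setMethod("show", "PeriEventTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "PeriEventTensor '%s': %d neurons x %d trials x %d bins [%g, %g] s%s\n",
    object@eventClass, d[1], d[2], d[3], object@binEdges[1],
    object@binEdges[length(object@binEdges)],
    if (object@zScored) " (Z-scored)" else " (raw)"))
})

#' @describeIn PeriEventTensor-class number of neurons.
#' @param object a `PeriEventTensor`.
#' @export
nNeurons <- function(object) dim(object@values)[1]

#' @describeIn PeriEventTensor-class number of trials.
#' @export
nTrials <- function(object) dim(object@values)[2]

#' @describeIn PeriEventTensor-class peri-event bin centers (s).
#' @export
binCenters <- function(object) {
  e <- object@binEdges
  (e[-1] + e[-length(e)]) / 2
}

#' @describeIn PeriEventTensor-class the underlying array.
#' @export
tensorValues <- function(object) object@values

#' @describeIn PeriEventTensor-class neuron identifiers.
#' @export
tensorNeuronIds <- function(object) object@neuronIds

# logical bin masks for the two windows
baselineBins <- function(object) {
  c <- binCenters(object)
  c >= object@baselineWindow[1] & c < object@baselineWindow[2]
}
responseBins <- function(object) {
  c <- binCenters(object)
  c >= object@responseWindow[1] & c < object@responseWindow[2]
}

#' PseudoPopulationDataset: resampled trial-by-neuron feature matrices
#'
#' Pseudo-simultaneous populations: for each resample, per-neuron trials are
#' drawn with replacement independently per class and stacked into a
#' pseudo-trial x neuron feature matrix, treating neurons recorded in
#' different animals as if simultaneous.
#'
#' @slot resamples list; each element has `x` (pseudo-trials x neurons
#'   matrix) and `y` (factor of class labels, balanced).
#' @slot provenance data.frame with one row per neuron (`neuron`, `animal`,
#'   `group`).
#' @slot nTrialsPerClass pseudo-trials sampled per class.
#' @slot seed integer seed the dataset was built with.
#' @export
setClass("PseudoPopulationDataset", representation(
  resamples = "list", provenance = "data.frame",
  nTrialsPerClass = "integer", seed = "integer"))

setValidity("PseudoPopulationDataset", function(object) {
  for (r in object@resamples) {
    if (!all(c("x", "y") %in% names(r))) return("each resample needs x and y")
    if (nrow(r$x) != length(r$y)) return("x rows must match label length")
    if (length(unique(table(r$y))) > 1L) return("classes must be balanced within a resample")
    if (!all(is.finite(r$x))) return("features must be finite")
  }
  TRUE
})

setMethod("show", "PseudoPopulationDataset", function(object) {
  n <- length(object@resamples)
  d <- if (n) dim(object@resamples[[1]]$x) else c(0L, 0L)
  cat(sprintf(
    "PseudoPopulationDataset: %d resamples of %d pseudo-trials x %d neurons\n",
    n, d[1], d[2]))
})

#' DecodingResult: cross-validated accuracies per resample
#'
#' @slot accuracies mean held-out accuracy per resample, in `[0, 1]`.
#' @slot nullAccuracies matrix (resamples x shuffles) of label-shuffle null
#'   accuracies; 0 columns when no shuffle control was run.
#' @slot group group label (e.g. `"BLA-mPFC"`).
#' @export
setClass("DecodingResult", representation(
  accuracies = "numeric", nullAccuracies = "matrix", group = "character"))

setValidity("DecodingResult", function(object) {
  a <- c(object@accuracies, object@nullAccuracies)
  if (length(a) && (any(a < 0) || any(a > 1))) return("accuracies must lie in [0, 1]")
  TRUE
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult (%s): %d resamples, mean accuracy %.3f",
              object@group, length(object@accuracies),
              mean(object@accuracies)))
  if (ncol(object@nullAccuracies))
    cat(sprintf(", %d shuffles (null mean %.3f)", ncol(object@nullAccuracies),
                mean(object@nullAccuracies)))
  cat("\n")
})

#' @describeIn DecodingResult-class per-resample accuracies.
#' @param object a `DecodingResult`.
#' @export
decodingAccuracies <- function(object) object@accuracies

#' IdentityMap: cross-session neuron identity bookkeeping
#'
#' @slot rows data.frame (`globalId`, `session`, `localId`): which
#'   within-session neuron corresponds to which global neuron identity.
#' @slot sessions ordered session ids.
#' @export
setClass("IdentityMap", representation(rows = "data.frame", sessions = "character"))

setValidity("IdentityMap", function(object) {
  r <- object@rows
  if (!all(c("globalId", "session", "localId") %in% names(r)))
    return("rows must have columns globalId, session, localId")
  if (anyDuplicated(r[, c("session", "localId")]))
    return("(session, localId) pairs must be unique")
  if (anyDuplicated(r[, c("session", "globalId")]))
    return("a globalId may appear at most once per session")
  if (!all(r$session %in% object@sessions))
    return("rows refer to unknown sessions")
  TRUE
})

#' @rdname IdentityMap-class
#' @param rows data.frame (globalId, session, localId).
#' @param sessions character vector of session ids.
#' @return An `IdentityMap`.
#' @export
IdentityMap <- function(rows, sessions = sort(unique(rows$session))) {
  rows$globalId <- as.character(rows$globalId)
  rows$session <- as.character(rows$session)
  rows$localId <- as.character(rows$localId)
  new("IdentityMap", rows = rows, sessions = as.character(sessions))
}

setMethod("show", "IdentityMap", function(object) {
  cat(sprintf("IdentityMap: %d global ids over %d sessions\n",
              length(unique(object@rows$globalId)), length(object@sessions)))
})

#' @describeIn IdentityMap-class the (globalId, session, localId) table.
#' @param object an `IdentityMap`.
#' @export
identityRows <- function(object) object@rows

#' FunctionalClustering: hierarchical clustering of neural time courses
#'
#' @slot clusterIds named integer vector (neuron id -> cluster id, 1..k,
#'   relabeled by descending cluster-mean peak).
#' @slot tree the `hclust` linkage tree.
#' @slot clusterMeans k x bins matrix of per-cluster mean time courses.
#' @slot binCentersS peri-event bin centers (s).
#' @slot silhouette mean silhouette width at the chosen k.
#' @export
setClass("FunctionalClustering", representation(
  clusterIds = "integer", tree = "ANY", clusterMeans = "matrix",
  binCentersS = "numeric", silhouette = "numeric"))

setValidity("FunctionalClustering", function(object) {
  k <- nrow(object@clusterMeans)
  if (length(object@clusterIds) && !all(object@clusterIds %in% seq_len(k)))
    return("cluster ids must partition neurons into 1..k")
  TRUE
})

setMethod("show", "FunctionalClustering", function(object) {
  cat(sprintf(
    "FunctionalClustering: %d neurons in %d clusters (mean silhouette %.3f)\n",
    length(object@clusterIds), nrow(object@clusterMeans), object@silhouette))
})

#' @describeIn FunctionalClustering-class neuron-to-cluster assignment.
#' @param object a `FunctionalClustering`.
#' @export
clusterAssignments <- function(object) object@clusterIds
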