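#' @include AllClasses.R
NULL

#' @export
setGeneric("percentWins", function(record, mouse) standardGeneric("percentWins"))

#' @export
setGeneric("assignRanks", function(record, ...) standardGeneric("assignRanks"))

#' @export
setGeneric("segmentBouts", function(stream, ...) standardGeneric("segmentBouts"))

#' @export
setGeneric("headBodyDistance", function(session) standardGeneric("headBodyDistance"))

#' @export
setGeneric("approachAngle", function(session) standardGeneric("approachAngle"))

#' @export
setGeneric("interactionTime", function(series) standardGeneric("interactionTime"))

#' @export
setGeneric("zscoreBaseline", function(tensor, ...) standardGeneric("zscoreBaseline"))

#' @export
setGeneric("classifyResponses", function(tensor, ...) standardGeneric("classifyResponses"))

#' @export
setGeneric("coregistrationRate", function(map, ...) standardGeneric("coregistrationRate"))
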