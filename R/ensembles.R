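#' @include AllClasses.R AllGenerics.R
NULL

#' Co-registration rate of an identity map
#'
#' Fraction of global neuron identities present in every listed session,
#' relative to the mean per-session neuron count (so "30% co-registered"
#' means 30% of a typical session's neurons were tracked across all
#' sessions).
#'
#' @param map an [IdentityMap-class].
#' @param sessions sessions that must all contain the neuron (default:
#'   every session in the map).
#' @return Numeric fraction; the `"detail"` attribute records the counts
#'   used.
#' @export
setMethod("coregistrationRate", "IdentityMap", function(map, sessions = NULL) {
  if (is.null(sessions)) sessions <- map@sessions
  if (!length(sessions)) stop("session subset must be non-empty")
  unknown <- setdiff(sessions, map@sessions)
  if (length(unknown))
    stop("unknown session(s): ", paste(unknown, collapse = ", "))
  r <- map@rows[map@rows$session %in% sessions, ]
  perSession <- table(factor(r$session, levels = sessions))
  spanning <- sum(tapply(r$session, r$globalId,
                         function(s) length(unique(s))) == length(sessions))
  rate <- spanning / mean(perSession)
  attr(rate, "detail") <- list(nSpanning = spanning,
                               meanPerSession = mean(perSession),
                               sessions = sessions)
  rate
})

#' Global ids co-registered across a set of sessions
#'
#' @param map an [IdentityMap-class].
#' @param sessions sessions the neuron must appear in.
#' @return character vector of global ids.
#' @export
coregisteredIds <- function(map, sessions = NULL) {
  if (is.null(sessions)) sessions <- map@sessions
  r <- map@rows[map@rows$session %in% sessions, ]
  cnt <- tapply(r$session, r$globalId, function(s) length(unique(s)))
  names(cnt)[cnt == length(sessions)]
}

#' Overlap of responsive ensembles across two conditions
#'
#' Counts, among neurons co-registered across the two sessions being
#' compared, how many are responsive (in the requested direction) in both
#' conditions, in each condition, and in total.
#'
#' @param labelsA,labelsB classification tables from [classifyResponses()]
#'   for the two conditions, with `neuronId` giving global ids present in
#'   `map`.
#' @param map an [IdentityMap-class].
#' @param sessionA,sessionB the sessions the two label sets came from.
#' @param direction `"excited"` (default) or `"inhibited"`; the two
#'   directions are analyzed separately.
#' @return one-row data.frame (`nCommon`, `nResponsiveA`, `nResponsiveB`,
#'   `nCoregistered`, `direction`).
#' @export
ensembleOverlap <- function(labelsA, labelsB, map, sessionA, sessionB,
                            direction = c("excited", "inhibited")) {
  direction <- match.arg(direction)
  co <- coregisteredIds(map, c(sessionA, sessionB))
  bad <- setdiff(c(labelsA$neuronId, labelsB$neuronId),
                 unique(map@rows$globalId))
  if (length(bad))
    stop("neuron(s) in labels but absent from the identity map: ",
         paste(utils::head(bad, 5), collapse = ", "))
  a <- intersect(labelsA$neuronId[labelsA$label == direction], co)
  b <- intersect(labelsB$neuronId[labelsB$label == direction], co)
  data.frame(nCommon = length(intersect(a, b)), nResponsiveA = length(a),
             nResponsiveB = length(b), nCoregistered = length(co),
             direction = direction)
}

#' Chi-square comparison of two ensemble-overlap proportions
#'
#' Compares the proportion of condition-A-responsive neurons that are also
#' responsive in condition B between two condition pairs, as a 2x2
#' chi-square test on (overlapping, non-overlapping) counts. Without
#' continuity correction the statistic equals the textbook
#' `sum((O - E)^2 / E)` on the 2x2 table; Yates correction is available
#' by flag and the setting is recorded in the output.
#'
#' @param row1,row2 one-row overlap tables from [ensembleOverlap()], or
#'   lists with `nCommon` and a denominator `nResponsiveA`.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list: `chi2`, `df`, `p`, `table`, `correct`.
#' @export
overlapChi2 <- function(row1, row2, correct = FALSE) {
  cnt <- function(r) c(overlap = r$nCommon,
                       nonOverlap = r$nResponsiveA - r$nCommon)
  tab <- rbind(pair1 = cnt(row1), pair2 = cnt(row2))
  if (any(rowSums(tab) == 0)) stop("zero-total row: no responsive neurons")
  if (any(tab < 0)) stop("overlap cannot exceed the responsive count")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab, correct = correct)
}
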