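#' @include AllClasses.R
NULL

# ---------------------------------------------------------------------------
# Plain-text interchange.  All tables are CSV with documented columns;
# calcium recordings live in a directory container of CSVs plus a JSON
# manifest.  Writers are deterministic byte-for-byte given equal inputs.
# ---------------------------------------------------------------------------

wcsv <- function(x, file) utils::write.csv(x, file, row.names = FALSE)

#' Read/write tube-test tournaments
#'
#' CSV columns: `day`, `mouseA`, `mouseB`, `winner`.
#'
#' @param file path.
#' @return `readTournament`: a [TournamentRecord-class].
#' @export
readTournament <- function(file)
  TournamentRecord(utils::read.csv(file, stringsAsFactors = FALSE))

#' @rdname readTournament
#' @param record a [TournamentRecord-class].
#' @export
writeTournament <- function(record, file) wcsv(record@trials, file)

#' Read/write lick streams
#'
#' Long CSV, one row per lick: `mouse`, `condition`, `spout`, `lickTimeS`.
#' A file may hold many sessions; `readLickStreams` returns one
#' [LickStream-class] per (mouse, condition, spout).
#'
#' @param file path.
#' @return `readLickStreams`: named list of [LickStream-class] objects
#'   (names `mouse_condition_spout`).
#' @export
readLickStreams <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  keys <- unique(d[, c("mouse", "condition", "spout")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    s <- d[d$mouse == keys$mouse[i] & d$condition == keys$condition[i] &
             d$spout == keys$spout[i], ]
    LickStream(sort(s$lickTimeS), spout = keys$spout[i],
               mouse = keys$mouse[i], condition = keys$condition[i])
  })
  names(out) <- paste(keys$mouse, keys$condition, keys$spout, sep = "_")
  out
}

#' @rdname readLickStreams
#' @param streams list of [LickStream-class] objects.
#' @export
writeLickStreams <- function(streams, file) {
  d <- do.call(rbind, lapply(streams, function(s)
    if (length(s@lickTimesS))
      data.frame(mouse = s@mouse, condition = s@condition, spout = s@spout,
                 lickTimeS = s@lickTimesS)
    else NULL))
  if (is.null(d))
    d <- data.frame(mouse = character(0), condition = character(0),
                    spout = character(0), lickTimeS = numeric(0))
  wcsv(d, file)
}

#' Read/write pose sessions
#'
#' Long CSV, one row per frame and node: `frame` (1-based), `node` (one of
#' `resident_head`, `resident_body`, `intruder_body`), `x`, `y` (pixels).
#' Missing coordinates mark invalid frames. The frame rate is not stored
#' in the CSV and must be supplied on read.
#'
#' @param file path.
#' @param fps frame rate of the recording.
#' @return `readPoseSession`: a [PoseSession-class].
#' @export
readPoseSession <- function(file, fps) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  n <- max(d$frame)
  grab <- function(node) {
    m <- matrix(NA_real_, n, 2)
    s <- d[d$node == node, ]
    m[s$frame, ] <- cbind(s$x, s$y)
    m
  }
  h <- grab("resident_head"); b <- grab("resident_body")
  i <- grab("intruder_body")
  valid <- rowSums(is.finite(cbind(h, b, i))) == 6L
  h[!valid, ] <- 0; b[!valid, ] <- 0; i[!valid, ] <- 0
  PoseSession(fps, h, b, i, validFrames = valid)
}

#' @rdname readPoseSession
#' @param session a [PoseSession-class].
#' @export
writePoseSession <- function(session, file) {
  n <- nFrames(session)
  d <- rbind(
    data.frame(frame = seq_len(n), node = "resident_head",
               x = session@residentHeadXy[, 1], y = session@residentHeadXy[, 2]),
    data.frame(frame = seq_len(n), node = "resident_body",
               x = session@residentBodyXy[, 1], y = session@residentBodyXy[, 2]),
    data.frame(frame = seq_len(n), node = "intruder_body",
               x = session@intruderBodyXy[, 1], y = session@intruderBodyXy[, 2]))
  d$x[!session@validFrames] <- NA; d$y[!session@validFrames] <- NA
  wcsv(d, file)
}

#' Read/write event series
#'
#' BED-like interval CSV: `label`, `startS`, `endS`.
#'
#' @param file path.
#' @return `readEventSeries`: an [EventSeries-class].
#' @export
readEventSeries <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  EventSeries(d[, c("startS", "endS")],
              label = if (nrow(d)) d$label[1] else "interaction")
}

#' @rdname readEventSeries
#' @param series an [EventSeries-class].
#' @export
writeEventSeries <- function(series, file) {
  iv <- series@intervals
  wcsv(data.frame(label = rep(series@label, nrow(iv)), startS = iv$startS,
                  endS = iv$endS), file)
}

#' Read/write identity maps
#'
#' CSV columns: `globalId`, `session`, `localId`.
#'
#' @param file path.
#' @return `readIdentityMap`: an [IdentityMap-class].
#' @export
readIdentityMap <- function(file)
  IdentityMap(utils::read.csv(file, stringsAsFactors = FALSE))

#' @rdname readIdentityMap
#' @param map an [IdentityMap-class].
#' @export
writeIdentityMap <- function(map, file)
  wcsv(map@rows[, c("globalId", "session", "localId")], file)

#' Read/write a calcium recording container
#'
#' A directory with `traces.csv` (wide: `neuronId` then one column per
#' frame), `events.csv` (`class`, `timeS`) and `manifest.json` (`fps`,
#' `nFrames`, `nNeurons`).
#'
#' @param dir container directory.
#' @return `readCalcium`: list with `traces` (neurons x frames matrix),
#'   `frameTimes`, `eventTimes` (named list).
#' @export
readCalcium <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  tr <- utils::read.csv(file.path(dir, "traces.csv"), check.names = FALSE)
  m <- as.matrix(tr[, -1, drop = FALSE])
  dimnames(m) <- list(tr$neuronId, NULL)
  ev <- utils::read.csv(file.path(dir, "events.csv"))
  list(traces = m, frameTimes = (seq_len(ncol(m)) - 1) / man$fps,
       eventTimes = split(ev$timeS, ev$class))
}

#' @rdname readCalcium
#' @param traces neurons x frames matrix (rownames = neuron ids).
#' @param fps sampling rate.
#' @param eventTimes named list of event-time vectors.
#' @export
writeCalcium <- function(traces, fps, eventTimes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- data.frame(neuronId = rownames(traces), signif(traces, 10),
                  check.names = FALSE)
  names(d)[-1] <- paste0("f", seq_len(ncol(traces)))
  wcsv(d, file.path(dir, "traces.csv"))
  ev <- data.frame(class = rep(names(eventTimes), lengths(eventTimes)),
                   timeS = unlist(eventTimes, use.names = FALSE))
  wcsv(ev, file.path(dir, "events.csv"))
  jsonlite::write_json(list(fps = fps, nFrames = ncol(traces),
                            nNeurons = nrow(traces)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Write a contrast report as JSON
#'
#' @param report a `contrastReport` from [conditionContrast()].
#' @param file output path.
#' @export
writeContrastReport <- function(report, file) {
  jsonlite::write_json(
    list(value = report$value, design = report$design,
         posthocAdjust = report$posthocAdjust, cells = report$cells,
         anova = report$anova, posthoc = report$posthoc,
         correlation = report$correlation),
    file, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(file)
}
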