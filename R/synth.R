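#' @include AllClasses.R utils.R
NULL

# ---------------------------------------------------------------------------
# Seeded synthetic-cohort generators.  Every generator takes an explicit
# seed, draws from a local RNG (no global state), and returns planted
# ground truth alongside the observable so downstream estimates can be
# audited against what was actually put in.
# ---------------------------------------------------------------------------

#' Cohort configuration
#'
#' Effect structure of a synthetic isolation-drinking cohort. Effects are
#' planted on total alcohol licks per session: licks increase down the
#' hierarchy (`rankEffectAlcohol` licks per rank step), social isolation
#' adds `isolationEffect` licks for dominants, and subordinates escalate by
#' an extra `rankXIsolation` licks per rank step. Mechanistically the
#' subordinate escalation is carried by licks per bout
#' (`lpbIsolationStep` extra licks per bout per rank step under isolation)
#' while the dominant escalation is carried by bout number.
#'
#' @param nCages number of cages (>= 1).
#' @param micePerCage mice per cage (default 4).
#' @param rankEffectAlcohol baseline licks added per rank step (rank 1 =
#'   dominant; positive means subordinates drink more).
#' @param isolationEffect licks added under social isolation at rank 1.
#' @param rankXIsolation additional isolation licks per rank step (the
#'   rank x isolation interaction).
#' @param lpbIsolationStep licks-per-bout added per rank step under
#'   isolation (subordinate mechanism).
#' @param baseTotalLicks expected alcohol licks of a rank-1 mouse before
#'   isolation.
#' @param baseLicksPerBout baseline mean licks per bout.
#' @param mouseSd between-mouse SD of the per-mouse lick intercept.
#' @param sessionMin session length in minutes.
#' @param skillSpread tube-test latent-skill gap between adjacent ranks
#'   (logistic scale); `Inf` makes wins deterministic.
#' @param seed integer seed.
#' @return list of class `CohortConfig`.
#' @export
cohortConfig <- function(nCages = 4L, micePerCage = 4L,
                         rankEffectAlcohol = 60, isolationEffect = 150,
                         rankXIsolation = 80, lpbIsolationStep = 1.0,
                         baseTotalLicks = 600, baseLicksPerBout = 8,
                         mouseSd = 100, sessionMin = 60,
                         skillSpread = 3, seed = 1L) {
  if (nCages < 1 || micePerCage < 1)
    stop("counts must be >= 1")
  structure(list(
    nCages = as.integer(nCages), micePerCage = as.integer(micePerCage),
    rankEffectAlcohol = rankEffectAlcohol, isolationEffect = isolationEffect,
    rankXIsolation = rankXIsolation, lpbIsolationStep = lpbIsolationStep,
    baseTotalLicks = baseTotalLicks, baseLicksPerBout = baseLicksPerBout,
    mouseSd = mouseSd, sessionMin = sessionMin, skillSpread = skillSpread,
    seed = as.integer(seed)), class = "CohortConfig")
}

#' Generate a tube-test tournament for one cage
#'
#' Every ordered pair of mice meets once per day for `days` days; the
#' winner of each trial is drawn from a Bradley-Terry model on latent
#' skill, where mouse `i` (intended rank `i`) has skill
#' `-skillSpread * (i - 1)`. With `skillSpread = Inf` the higher-skilled
#' mouse always wins; with 0 every trial is a coin flip.
#'
#' @param nMice number of mice (>= 2).
#' @param skillSpread latent skill gap between adjacent ranks.
#' @param days number of test days (default 3).
#' @param mouseIds optional ids (default `m1..mN`, in decreasing skill).
#' @param seed integer seed.
#' @return list: `record` (a [TournamentRecord-class]), `truth`
#'   (data.frame `mouse`, `trueRank`, `skill`).
#' @export
genTournament <- function(nMice = 4L, skillSpread = 3, days = 3L,
                          mouseIds = NULL, seed = 1L) {
  if (nMice < 2) stop("need at least two mice for a tournament")
  if (days < 1) stop("need at least one test day")
  if (is.null(mouseIds)) mouseIds <- paste0("m", seq_len(nMice))
  stopifnot(length(mouseIds) == nMice, !anyDuplicated(mouseIds))
  skill <- -skillSpread * (seq_len(nMice) - 1)
  pairs <- expand.grid(a = seq_len(nMice), b = seq_len(nMice))
  pairs <- pairs[pairs$a != pairs$b, ]
  trials <- withSeed(seed, {
    do.call(rbind, lapply(seq_len(days), function(day) {
      pWinA <- if (is.infinite(skillSpread)) {
        as.numeric(pairs$a < pairs$b)
      } else {
        stats::plogis(skill[pairs$a] - skill[pairs$b])
      }
      aWins <- stats::runif(nrow(pairs)) < pWinA
      data.frame(day = day, mouseA = mouseIds[pairs$a],
                 mouseB = mouseIds[pairs$b],
                 winner = ifelse(aWins, mouseIds[pairs$a], mouseIds[pairs$b]))
    }))
  })
  list(record = TournamentRecord(trials),
       truth = data.frame(mouse = mouseIds, trueRank = seq_len(nMice),
                          skill = skill))
}

#' Generate a bout-structured lick stream
#'
#' Bouts are placed through the session with between-bout gaps guaranteed
#' to be at least `gapFloorS`, which must exceed the largest possible
#' within-bout inter-lick interval, so the ground-truth bout structure is
#' unambiguous to any segmentation threshold between the two. The number
#' of bouts is Poisson with mean `boutRateMin * sessionS / 60` (truncated
#' only if the session cannot physically hold them), and lick counts per
#' bout are `minLicks + Poisson(licksPerBoutMean - minLicks)`.
#'
#' @param sessionS session duration (s).
#' @param boutRateMin expected bouts per minute.
#' @param licksPerBoutMean mean licks per bout (>= `minLicks`).
#' @param withinBoutIliS mean within-bout inter-lick interval (s).
#' @param iliJitterSd SD of Gaussian jitter on within-bout intervals,
#'   truncated at 3 SD; `withinBoutIliS + 3 * iliJitterSd` must stay below
#'   `gapFloorS`.
#' @param gapFloorS minimum between-bout gap (s).
#' @param minLicks minimum licks per bout.
#' @param nBouts optional exact bout count, overriding the Poisson draw.
#' @param fixedLicksPerBout optional exact per-bout lick count (recycled),
#'   overriding the Poisson draw.
#' @param spout,mouse,condition stream metadata.
#' @param seed integer seed.
#' @return list: `stream` (a [LickStream-class]), `truth` (data.frame
#'   `bout`, `startS`, `endS`, `nLicks`), `gapFloorS`.
#' @export
genLickStream <- function(sessionS = 3600, boutRateMin = 2,
                          licksPerBoutMean = 8, withinBoutIliS = 0.15,
                          iliJitterSd = 0.02, gapFloorS = 2, minLicks = 3L,
                          nBouts = NULL, fixedLicksPerBout = NULL,
                          spout = "alcohol", mouse = NA_character_,
                          condition = NA_character_, seed = 1L) {
  if (withinBoutIliS <= 0 || sessionS <= 0 || boutRateMin < 0)
    stop("durations and rates must be positive")
  maxIli <- withinBoutIliS + 3 * iliJitterSd
  if (maxIli >= gapFloorS)
    stop("overlapping-bout parameterization: within-bout intervals ",
         "(up to ", maxIli, " s) must stay below the gap floor (",
         gapFloorS, " s)")
  if (licksPerBoutMean < minLicks)
    stop("licksPerBoutMean must be at least minLicks")
  withSeed(seed, {
    nb <- if (!is.null(nBouts)) as.integer(nBouts) else
      stats::rpois(1, boutRateMin * sessionS / 60)
    emptyTruth <- data.frame(bout = integer(0), startS = numeric(0),
                             endS = numeric(0), nLicks = integer(0))
    if (nb == 0L) {
      list(stream = LickStream(numeric(0), spout, mouse, condition),
           truth = emptyTruth, gapFloorS = gapFloorS)
    } else {
    counts <- if (!is.null(fixedLicksPerBout)) {
      rep_len(as.integer(fixedLicksPerBout), nb)
    } else {
      minLicks + stats::rpois(nb, licksPerBoutMean - minLicks)
    }
    ilis <- lapply(counts, function(n) {
      if (n <= 1L) return(numeric(0))
      j <- pmin(3 * iliJitterSd, pmax(-3 * iliJitterSd,
                                      stats::rnorm(n - 1L, 0, iliJitterSd)))
      pmax(withinBoutIliS + j, 0.05 * withinBoutIliS)
    })
    durs <- vapply(ilis, sum, 0)
    # drop trailing bouts that cannot fit in the session
    need <- cumsum(durs) + (seq_len(nb) - 1L) * gapFloorS
    fit <- which(need <= sessionS)
    if (!length(fit)) stop("session too short to hold a single bout")
    nb <- max(fit)
    counts <- counts[seq_len(nb)]; ilis <- ilis[seq_len(nb)]
    durs <- durs[seq_len(nb)]
    slack <- sessionS - sum(durs) - (nb - 1L) * gapFloorS
    w <- stats::rgamma(nb + 1L, shape = 1)
    extra <- slack * w / sum(w)       # last share is unused session tail
    starts <- numeric(nb)
    t <- extra[1L]
    licks <- vector("list", nb)
    for (i in seq_len(nb)) {
      starts[i] <- t
      licks[[i]] <- t + cumsum(c(0, ilis[[i]]))
      t <- licks[[i]][counts[i]] + gapFloorS + extra[i + 1L]
    }
    truth <- data.frame(bout = seq_len(nb), startS = starts,
                        endS = vapply(licks, max, 0), nLicks = counts)
    list(stream = LickStream(unlist(licks), spout, mouse, condition),
         truth = truth, gapFloorS = gapFloorS)
    }
  })
}

#' Generate a two-animal pose session with planted interaction episodes
#'
#' The resident follows a smooth random walk near the arena center. During
#' planted episodes the intruder's body is placed within 60 px of the
#' resident's head and within a 135-degree approach cone, with enough
#' margin that keypoint jitter cannot flip the rule; outside episodes at
#' least one criterion is violated (the intruder is either far away or
#' behind the resident). Gaussian keypoint jitter is truncated at 2.5 SD
#' and coordinates are clamped to the arena.
#'
#' @param durationS session duration (s).
#' @param fps frame rate.
#' @param episodes data.frame with `startS`, `stopS` of planted interaction
#'   episodes; must be sorted, non-overlapping, inside the session.
#' @param arenaPx arena size `c(width, height)` in pixels (>= 480 each so
#'   the planted geometry fits).
#' @param noiseSd keypoint jitter SD in pixels (default 0.5).
#' @param seed integer seed.
#' @return list: `session` (a [PoseSession-class]), `truth` (list with
#'   `episodes` and logical `interactingFrames`; frame `i` covers
#'   `[(i-1)/fps, i/fps)` and counts as interacting iff its start time lies
#'   in an episode).
#' @export
genPoseSession <- function(durationS, fps, episodes = NULL,
                           arenaPx = c(600, 600), noiseSd = 0.5, seed = 1L) {
  if (fps <= 0 || durationS <= 0) stop("fps and duration must be positive")
  if (min(arenaPx) < 480)
    stop("arena too small for the planted geometry; need >= 480 px")
  if (is.null(episodes))
    episodes <- data.frame(startS = numeric(0), stopS = numeric(0))
  if (nrow(episodes)) {
    if (any(episodes$stopS <= episodes$startS) ||
        any(episodes$startS < 0) || any(episodes$stopS > durationS))
      stop("episodes must have positive duration and lie inside the session")
    if (nrow(episodes) > 1 &&
        any(episodes$startS[-1] < episodes$stopS[-nrow(episodes)]))
      stop("episodes must be sorted and non-overlapping")
  }
  nF <- round(durationS * fps)
  frameStart <- (seq_len(nF) - 1L) / fps
  inEp <- rep(FALSE, nF)
  for (i in seq_len(nrow(episodes)))
    inEp <- inEp | (frameStart >= episodes$startS[i] &
                      frameStart < episodes$stopS[i])
  headLen <- 30
  withSeed(seed, {
    center <- arenaPx / 2
    walk <- function() {
      x <- cumsum(stats::rnorm(nF, 0, 2))
      pmin(80, pmax(-80, x))
    }
    body <- cbind(center[1] + walk(), center[2] + walk())
    phi <- cumsum(stats::rnorm(nF, 0, 0.1))      # heading angle (rad)
    head <- body + headLen * cbind(cos(phi), sin(phi))
    d <- numeric(nF); delta <- numeric(nF)
    nIn <- sum(inEp); nOut <- nF - nIn
    # inside episodes: close and in front, with margin against jitter
    d[inEp] <- stats::runif(nIn, 18, 50)
    delta[inEp] <- stats::runif(nIn, -100, 100) * pi / 180
    # outside: far away (70%) or close but behind (30%)
    far <- stats::runif(nOut) < 0.7
    dOut <- ifelse(far, stats::runif(nOut, 75, 180), stats::runif(nOut, 18, 50))
    delOut <- ifelse(far, stats::runif(nOut, -180, 180),
                     sample(c(-1, 1), nOut, replace = TRUE) *
                       stats::runif(nOut, 160, 180)) * pi / 180
    d[!inEp] <- dOut; delta[!inEp] <- delOut
    intruder <- head + d * cbind(cos(phi + delta), sin(phi + delta))
    jitter <- function(m) {
      j <- matrix(stats::rnorm(length(m), 0, noiseSd), ncol = 2)
      j <- pmin(2.5 * noiseSd, pmax(-2.5 * noiseSd, j))
      m <- m + j
      cbind(pmin(arenaPx[1], pmax(0, m[, 1])), pmin(arenaPx[2], pmax(0, m[, 2])))
    }
    session <- PoseSession(fps, jitter(head), jitter(body), jitter(intruder))
    list(session = session,
         truth = list(episodes = episodes, interactingFrames = inEp))
  })
}

#' Generate a calcium-trace population with planted event responses
#'
#' Excited neurons add a positive event-locked transient (instantaneous
#' rise, single-exponential decay with time constant `kernelTauS`) on a
#' Gaussian noise floor; inhibited neurons add the negative transient;
#' the remainder is pure noise. Amplitude is expressed in Z units of the
#' noise floor (raw amplitude `amplitudeZ * noiseSd`, or `amplitudeZ`
#' itself when `noiseSd = 0`). Response ensembles for different event
#' classes are disjoint.
#'
#' @param nNeurons number of neurons.
#' @param eventTimes numeric vector of event times (s), or a named list of
#'   such vectors (one per event class).
#' @param fracExcited,fracInhibited fraction of neurons excited/inhibited
#'   per event class; total allocated fractions must be <= 1.
#' @param amplitudeZ transient peak amplitude in noise-SD units.
#' @param kernelTauS decay time constant (s).
#' @param noiseSd Gaussian noise SD (trace units).
#' @param fps sampling rate of the traces.
#' @param durationS recording length (default: last event + 10 s).
#' @param seed integer seed.
#' @return list: `traces` (neurons x frames matrix, rownames = neuron ids),
#'   `frameTimes`, `eventTimes` (named list), `truth` (data.frame
#'   `neuronId`, `class` in excited/inhibited/none, `eventClass`,
#'   `amplitudeZ`).
#' @export
genCalciumPopulation <- function(nNeurons, eventTimes, fracExcited = 0.2,
                                 fracInhibited = 0.2, amplitudeZ = 3,
                                 kernelTauS = 1.0, noiseSd = 1, fps = 20,
                                 durationS = NULL, seed = 1L) {
  if (fps <= 0) stop("fps must be positive")
  if (!is.list(eventTimes)) eventTimes <- list(event = eventTimes)
  nClass <- length(eventTimes)
  if (nClass * (fracExcited + fracInhibited) > 1 + 1e-12)
    stop("response fractions exceed 1: cannot allocate disjoint ensembles")
  if (is.null(durationS)) durationS <- max(unlist(eventTimes)) + 10
  nF <- round(durationS * fps)
  frameTimes <- (seq_len(nF) - 1L) / fps
  ampRaw <- amplitudeZ * if (noiseSd > 0) noiseSd else 1
  withSeed(seed, {
    traces <- matrix(stats::rnorm(nNeurons * nF, 0, noiseSd), nrow = nNeurons)
    ids <- sprintf("n%03d", seq_len(nNeurons))
    rownames(traces) <- ids
    truth <- data.frame(neuronId = ids, class = "none",
                        eventClass = NA_character_, amplitudeZ = 0)
    pool <- sample.int(nNeurons)
    take <- function(n) {
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    addKernel <- function(i, events, sign) {
      for (te in events) {
        idx <- which(frameTimes >= te)
        traces[i, idx] <<- traces[i, idx] +
          sign * ampRaw * exp(-(frameTimes[idx] - te) / kernelTauS)
      }
    }
    for (cl in names(eventTimes)) {
      nExc <- round(fracExcited * nNeurons)
      nInh <- round(fracInhibited * nNeurons)
      exc <- take(nExc); inh <- take(nInh)
      for (i in exc) addKernel(i, eventTimes[[cl]], +1)
      for (i in inh) addKernel(i, eventTimes[[cl]], -1)
      truth$class[exc] <- "excited"; truth$class[inh] <- "inhibited"
      truth$eventClass[c(exc, inh)] <- cl
      truth$amplitudeZ[exc] <- amplitudeZ
      truth$amplitudeZ[inh] <- -amplitudeZ
    }
    list(traces = traces, frameTimes = frameTimes, eventTimes = eventTimes,
         truth = truth)
  })
}

#' Generate a cross-session neuron identity map
#'
#' Each session records `nNeuronsPerSession` neurons. A Bernoulli
#' (`coregistrationRate`) subset of one session's worth of global
#' identities is tracked across every session; the remaining per-session
#' slots are filled by identities spanning strict subsets of sessions.
#'
#' @param nSessions number of sessions (>= 2 unless rate is 1).
#' @param nNeuronsPerSession neurons recorded per session.
#' @param coregistrationRate probability a neuron is tracked across all
#'   sessions, in `[0, 1]`.
#' @param seed integer seed.
#' @return list: `map` (an [IdentityMap-class]), `truth` (data.frame
#'   `globalId`, `coregistered`).
#' @export
genIdentityMap <- function(nSessions = 4L, nNeuronsPerSession = 200L,
                           coregistrationRate = 0.3, seed = 1L) {
  if (coregistrationRate < 0 || coregistrationRate > 1)
    stop("coregistrationRate must lie in [0, 1]")
  if (nSessions < 2 && coregistrationRate < 1)
    stop("partial co-registration needs at least two sessions")
  sessions <- paste0("s", seq_len(nSessions))
  withSeed(seed, {
    nCoreg <- stats::rbinom(1, nNeuronsPerSession, coregistrationRate)
    gid <- 0L
    rows <- vector("list", 0)
    coregIds <- character(0)
    if (nCoreg > 0) {
      coregIds <- sprintf("g%05d", seq_len(nCoreg))
      gid <- nCoreg
      rows[[1]] <- expand.grid(globalId = coregIds, session = sessions,
                               stringsAsFactors = FALSE)
    }
    deficit <- rep(nNeuronsPerSession - nCoreg, nSessions)
    part <- list()
    while (any(deficit > 0)) {
      open <- which(deficit > 0)
      size <- sample.int(min(nSessions - 1L, length(open)), 1)
      pick <- open[order(-deficit[open], stats::runif(length(open)))][seq_len(size)]
      gid <- gid + 1L
      part[[length(part) + 1L]] <-
        data.frame(globalId = sprintf("g%05d", gid), session = sessions[pick])
      deficit[pick] <- deficit[pick] - 1L
    }
    rows <- do.call(rbind, c(rows, part))
    # per-session local ids in randomized order
    rows <- rows[order(rows$session, stats::runif(nrow(rows))), ]
    rows$localId <- stats::ave(seq_len(nrow(rows)), rows$session,
                               FUN = seq_along)
    rows$localId <- sprintf("c%04d", rows$localId)
    allIds <- sprintf("g%05d", seq_len(gid))
    list(map = IdentityMap(rows, sessions),
         truth = data.frame(globalId = allIds,
                            coregistered = allIds %in% coregIds))
  })
}

#' Generate a full synthetic cohort
#'
#' Builds, for every cage, a tube-test tournament and per-mouse alcohol
#' and water lick streams before (`pre_SI`) and during (`SI`) social
#' isolation, with the effect structure of [cohortConfig()] planted on the
#' alcohol streams: expected total licks
#' `baseTotalLicks + mouseIntercept + rankEffectAlcohol*(rank-1) +
#' SI*(isolationEffect + rankXIsolation*(rank-1))`, realized through a
#' licks-per-bout increase for subordinates (`lpbIsolationStep` per rank
#' step under SI) and a bout-rate increase for dominants. Water streams
#' carry no rank or isolation effect.
#'
#' @param config a [cohortConfig()].
#' @return list: `config`, `mice` (data.frame `mouse`, `cage`, `trueRank`,
#'   `lickIntercept`), `tournaments` (per cage, see [genTournament()]),
#'   `streams` (list of [LickStream-class]), `lickTruth` (per-stream bout
#'   ground truth).
#' @export
genCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  sessionS <- config$sessionMin * 60
  mice <- list(); tournaments <- list(); streams <- list(); lickTruth <- list()
  for (cg in seq_len(config$nCages)) {
    ids <- sprintf("c%02dm%d", cg, seq_len(config$micePerCage))
    tournaments[[cg]] <- genTournament(
      nMice = config$micePerCage, skillSpread = config$skillSpread,
      mouseIds = ids, seed = childSeed(config$seed, cg))
    intercept <- withSeed(childSeed(config$seed, 1000L + cg),
                          stats::rnorm(config$micePerCage, 0, config$mouseSd))
    mice[[cg]] <- data.frame(mouse = ids, cage = cg,
                             trueRank = seq_len(config$micePerCage),
                             lickIntercept = intercept)
    for (j in seq_len(config$micePerCage)) {
      step <- j - 1
      for (si in c(0, 1)) {
        cond <- if (si) "SI" else "pre_SI"
        target <- max(50, config$baseTotalLicks + intercept[j] +
                        config$rankEffectAlcohol * step +
                        si * (config$isolationEffect +
                                config$rankXIsolation * step))
        lpb <- config$baseLicksPerBout + si * config$lpbIsolationStep * step
        rate <- target / (lpb * config$sessionMin)
        key <- paste(ids[j], cond, "alcohol", sep = "_")
        g <- genLickStream(sessionS = sessionS, boutRateMin = rate,
                           licksPerBoutMean = lpb, spout = "alcohol",
                           mouse = ids[j], condition = cond,
                           seed = childSeed(config$seed, 2000L + 100L * cg +
                                              4L * j + si))
        streams[[key]] <- g$stream; lickTruth[[key]] <- g$truth
        keyW <- paste(ids[j], cond, "water", sep = "_")
        gw <- genLickStream(sessionS = sessionS,
                            boutRateMin = 400 / (config$baseLicksPerBout *
                                                   config$sessionMin),
                            licksPerBoutMean = config$baseLicksPerBout,
                            spout = "water", mouse = ids[j], condition = cond,
                            seed = childSeed(config$seed, 60000L + 100L * cg +
                                               4L * j + si))
        streams[[keyW]] <- gw$stream; lickTruth[[keyW]] <- gw$truth
      }
    }
  }
  list(config = config, mice = do.call(rbind, mice),
       tournaments = tournaments, streams = streams, lickTruth = lickTruth)
}

#' Microstructure summaries of a synthetic cohort
#'
#' Runs the full behavioral chain on a generated cohort: ranks each cage
#' from its tournament, segments every lick stream into bouts, and
#' summarizes the microstructure per mouse x condition x spout.
#'
#' @param cohort output of [genCohort()].
#' @param iliThresholdS,minLicks bout criterion passed to [segmentBouts()].
#' @return data.frame with columns `mouse`, `cage`, `condition`, `spout`,
#'   `totalLicks`, `nBouts`, `meanLicksPerBout`, `rank` (assigned from the
#'   tournament), `percentWins`, `trueRank`.
#' @export
cohortSummaries <- function(cohort, iliThresholdS = 1.0, minLicks = 3L) {
  ranks <- do.call(rbind, lapply(cohort$tournaments, function(t)
    assignRanks(t$record)))
  out <- do.call(rbind, lapply(cohort$streams, function(s) {
    b <- segmentBouts(s, iliThresholdS = iliThresholdS, minLicks = minLicks)
    microstructureSummary(b, s)
  }))
  out$rank <- ranks$rank[match(out$mouse, ranks$mouse)]
  out$percentWins <- ranks$percentWins[match(out$mouse, ranks$mouse)]
  out$cage <- cohort$mice$cage[match(out$mouse, cohort$mice$mouse)]
  out$trueRank <- cohort$mice$trueRank[match(out$mouse, cohort$mice$mouse)]
  rownames(out) <- NULL
  out
}
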