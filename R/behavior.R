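#' @include AllClasses.R AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# Tube-test rank scoring
# ---------------------------------------------------------------------------

#' Percent wins of one mouse in a tube-test tournament
#'
#' The rank score of the tube dominance test: 100 x (trials won) /
#' (trials participated in), pooled over all test days.
#'
#' @param record a [TournamentRecord-class].
#' @param mouse mouse id; must appear in at least one trial.
#' @return Percentage in `[0, 100]`.
#' @export
setMethod("percentWins", "TournamentRecord", function(record, mouse) {
  tr <- record@trials
  inTrial <- tr$mouseA == mouse | tr$mouseB == mouse
  if (!any(inTrial))
    stop("mouse '", mouse, "' does not appear in the tournament record")
  100 * sum(tr$winner[inTrial] == mouse) / sum(inTrial)
})

#' Assign social ranks from a tournament record
#'
#' Ranks mice by percent wins (rank 1 = dominant, highest percent wins).
#' Ties are broken by head-to-head wins between the tied mice, then by
#' lexicographic mouse id, so the ranking is deterministic.
#'
#' @param record a [TournamentRecord-class] with at least two mice.
#' @return data.frame with columns `mouse`, `percentWins`, `rank`; ranks
#'   are a permutation of `1..N` and non-increasing in `percentWins`.
#' @export
setMethod("assignRanks", "TournamentRecord", function(record, ...) {
  tr <- record@trials
  mice <- sort(unique(c(tr$mouseA, tr$mouseB)))
  if (length(mice) < 2L) stop("need at least two mice to rank")
  pw <- vapply(mice, function(m) percentWins(record, m), 0)
  # head-to-head wins against the other mice tied at the same percent wins
  h2h <- vapply(seq_along(mice), function(i) {
    tied <- setdiff(mice[abs(pw - pw[i]) < 1e-12], mice[i])
    if (!length(tied)) return(0)
    sub <- tr[(tr$mouseA == mice[i] & tr$mouseB %in% tied) |
              (tr$mouseB == mice[i] & tr$mouseA %in% tied), , drop = FALSE]
    sum(sub$winner == mice[i])
  }, 0)
  ord <- order(-pw, -h2h, mice)
  out <- data.frame(mouse = mice[ord], percentWins = pw[ord],
                    rank = seq_along(mice), row.names = NULL)
  out
})

# ---------------------------------------------------------------------------
# Lick microstructure
# ---------------------------------------------------------------------------

#' Segment a lick stream into bouts
#'
#' Consecutive licks separated by at most `iliThresholdS` belong to one
#' bout; runs with fewer than `minLicks` licks are discarded.
#'
#' @param stream a [LickStream-class].
#' @param iliThresholdS inter-lick-interval threshold (s), > 0. A pause
#'   longer than this ends the bout.
#' @param minLicks minimum licks per bout (>= 1); shorter runs are dropped.
#' @return data.frame (`bout`, `startS`, `endS`, `nLicks`, `spout`):
#'   non-overlapping, ordered bouts.
#' @export
setMethod("segmentBouts", "LickStream", function(stream, iliThresholdS = 1.0,
                                                 minLicks = 3L) {
  stopifnot(iliThresholdS > 0, minLicks >= 1)
  t <- stream@lickTimesS
  if (is.unsorted(t, strictly = TRUE))
    stop("lick times must be strictly sorted")
  empty <- data.frame(bout = integer(0), startS = numeric(0),
                      endS = numeric(0), nLicks = integer(0),
                      spout = character(0))
  if (!length(t)) return(empty)
  runId <- cumsum(c(1, diff(t) > iliThresholdS))
  starts <- tapply(t, runId, min)
  ends <- tapply(t, runId, max)
  n <- as.integer(table(runId))
  keep <- n >= minLicks
  if (!any(keep)) return(empty)
  data.frame(bout = seq_len(sum(keep)), startS = as.numeric(starts[keep]),
             endS = as.numeric(ends[keep]), nLicks = n[keep],
             spout = stream@spout, row.names = NULL)
})

#' Summarize lick microstructure
#'
#' @param bouts bout table from [segmentBouts()], derived from `stream`.
#' @param stream the [LickStream-class] the bouts came from.
#' @return data.frame with one row: `totalLicks`, `nBouts`,
#'   `meanLicksPerBout` (`NA` when there are no bouts), `spout`, `mouse`,
#'   `condition`.
#' @export
microstructureSummary <- function(bouts, stream) {
  if (nrow(bouts) && !all(bouts$spout == stream@spout))
    stop("bout table and stream disagree on spout label")
  nb <- nrow(bouts)
  data.frame(
    totalLicks = length(stream@lickTimesS),
    nBouts = nb,
    meanLicksPerBout = if (nb) sum(bouts$nLicks) / nb else NA_real_,
    spout = stream@spout, mouse = stream@mouse,
    condition = stream@condition, row.names = NULL)
}

# ---------------------------------------------------------------------------
# Condition x rank contrasts
# ---------------------------------------------------------------------------

# Flatten summary.aov / summary.aovlist into one data.frame.
flattenAov <- function(fit) {
  s <- summary(fit)
  tabs <- if (inherits(fit, "aovlist")) lapply(s, function(x) x[[1]]) else s
  out <- do.call(rbind, lapply(tabs, function(tab) {
    tab <- as.data.frame(tab)
    data.frame(term = trimws(rownames(tab)), df = tab$Df, sumSq = tab$`Sum Sq`,
               F = if ("F value" %in% names(tab)) tab$`F value` else NA_real_,
               p = if ("Pr(>F)" %in% names(tab)) tab$`Pr(>F)` else NA_real_,
               row.names = NULL)
  }))
  out <- out[out$term != "Residuals", , drop = FALSE]
  # an exactly zero effect sum of squares is a zero F even when the
  # residual variance is also zero (constant data)
  zero <- !is.na(out$sumSq) & out$sumSq < 1e-12
  out$F[zero] <- 0
  out$p[zero] <- 1
  rownames(out) <- NULL
  out
}

#' Two-factor condition-by-rank contrast of microstructure summaries
#'
#' Computes per-cell means and SEM, a two-factor ANOVA
#' (condition/stimulation x rank or group), Sidak-adjusted post-hoc
#' pairwise comparisons of condition within each rank, and a rank-vs-value
#' correlation report. When every mouse appears under both condition
#' levels the ANOVA uses a repeated-measures error structure
#' (`Error(mouse/condition)`), which is the design of a within-subject
#' isolation challenge; otherwise a between-subjects fit is used.
#'
#' @param data data.frame with columns `mouse`, `condition`, `rank` and the
#'   response named by `value`; every condition x rank cell must be
#'   non-empty.
#' @param value name of the response column (default `"totalLicks"`).
#' @param posthocAdjust multiplicity adjustment for post-hoc comparisons
#'   (default `"sidak"`; any method `emmeans` accepts).
#' @param rankAsPercentWins if TRUE, correlations use `percentWins` instead
#'   of the integer rank as regressor (requires a `percentWins` column).
#' @return list of class `contrastReport`: `cells` (mean, sem, n per cell),
#'   `anova` (term, df, sumSq, F, p), `posthoc` (data.frame), `correlation`
#'   (per condition: r, r2, p), `design` (`"within"` or `"between"`).
#' @export
conditionContrast <- function(data, value = "totalLicks",
                              posthocAdjust = "sidak",
                              rankAsPercentWins = FALSE) {
  stopifnot(all(c("mouse", "condition", "rank", value) %in% names(data)))
  rankNum <- suppressWarnings(as.numeric(as.character(data$rank)))
  if (all(is.na(rankNum))) rankNum <- as.numeric(factor(data$rank))
  data <- data.frame(mouse = factor(data$mouse),
                     condition = factor(data$condition),
                     rank = factor(data$rank),
                     y = data[[value]],
                     rankNum = rankNum,
                     pw = if (rankAsPercentWins) data$percentWins else NA_real_)
  cells <- expand.grid(condition = levels(data$condition),
                       rank = levels(data$rank))
  cells$n <- mapply(function(c, r) sum(data$condition == c & data$rank == r),
                    cells$condition, cells$rank)
  if (any(cells$n == 0))
    stop("empty condition x rank cell: no residual degrees of freedom for ",
         "the two-factor model; every cell needs observations")
  cells$mean <- mapply(function(c, r) mean(data$y[data$condition == c & data$rank == r]),
                       cells$condition, cells$rank)
  cells$sem <- mapply(function(c, r) sem(data$y[data$condition == c & data$rank == r]),
                      cells$condition, cells$rank)

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  multiRank <- nlevels(data$rank) > 1L
  within <- all(table(data$mouse, data$condition) == 1L) &&
    nlevels(data$condition) > 1L
  form <- if (multiRank) y ~ condition * rank else y ~ condition
  if (within) {
    fit <- stats::aov(stats::update(form, . ~ . + Error(mouse / condition)),
                      data = data)
    design <- "within"
  } else {
    fit <- stats::aov(form, data = data)
    design <- "between"
  }
  anovaTab <- flattenAov(fit)

  posthoc <- tryCatch({
    emm <- if (multiRank) {
      emmeans::emmeans(fit, ~ condition | rank, data = data)
    } else {
      emmeans::emmeans(fit, ~ condition, data = data)
    }
    as.data.frame(summary(graphics::pairs(emm), adjust = posthocAdjust))
  }, error = function(e) data.frame())

  reg <- if (rankAsPercentWins) data$pw else data$rankNum
  correlation <- do.call(rbind, lapply(levels(data$condition), function(cond) {
    i <- data$condition == cond
    if (length(unique(reg[i])) < 2L || length(unique(data$y[i])) < 2L) {
      return(data.frame(condition = cond, r = NA_real_, r2 = NA_real_,
                        p = NA_real_))
    }
    ct <- stats::cor.test(reg[i], data$y[i])
    data.frame(condition = cond, r = unname(ct$estimate),
               r2 = unname(ct$estimate)^2, p = ct$p.value)
  }))

  structure(list(cells = cells, anova = anovaTab, posthoc = posthoc,
                 correlation = correlation, design = design,
                 value = value, posthocAdjust = posthocAdjust),
            class = "contrastReport")
}

#' @export
print.contrastReport <- function(x, ...) {
  cat("Condition x rank contrast of", x$value, "(", x$design, "design )\n\n")
  cat("Cell means:\n"); print(x$cells, digits = 4)
  cat("\nANOVA:\n"); print(x$anova, digits = 4)
  cat("\nRank correlation:\n"); print(x$correlation, digits = 4)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Cued-trial bookkeeping
# ---------------------------------------------------------------------------

#' Build a trial table from cue onsets
#'
#' In the cued two-bottle-choice task a cue light signals availability of
#' the bottles for a fixed access period, after which they are retracted.
#'
#' @param cueOnsets sorted cue onset times (s).
#' @param accessDurationS access-window duration (s); must be shorter than
#'   the minimum inter-cue interval so windows cannot overlap.
#' @param stimulatedFlags optional logical vector (per trial) marking
#'   stimulation trials; defaults to all FALSE.
#' @return data.frame (`trial`, `cueOnsetS`, `accessStartS`, `accessEndS`,
#'   `stimulated`) with disjoint access windows.
#' @export
trialsFromCues <- function(cueOnsets, accessDurationS, stimulatedFlags = NULL) {
  stopifnot(accessDurationS > 0)
  if (is.unsorted(cueOnsets, strictly = TRUE))
    stop("cue onsets must be strictly sorted")
  if (length(cueOnsets) > 1L && accessDurationS >= min(diff(cueOnsets)))
    stop("access windows overlap: access duration must be below the ",
         "minimum inter-cue interval")
  if (is.null(stimulatedFlags)) stimulatedFlags <- rep(FALSE, length(cueOnsets))
  stopifnot(length(stimulatedFlags) == length(cueOnsets))
  data.frame(trial = seq_along(cueOnsets), cueOnsetS = cueOnsets,
             accessStartS = cueOnsets,
             accessEndS = cueOnsets + accessDurationS,
             stimulated = as.logical(stimulatedFlags))
}

#' Assign licks to cued trials
#'
#' @param lickTimesS lick times (s).
#' @param trials trial table from [trialsFromCues()].
#' @return integer vector: the trial whose access window
#'   (`[accessStartS, accessEndS)`) contains each lick, or `NA` for licks
#'   in the intertrial period. Each lick maps to at most one trial.
#' @export
licksToTrials <- function(lickTimesS, trials) {
  out <- rep(NA_integer_, length(lickTimesS))
  for (i in seq_len(nrow(trials))) {
    hit <- lickTimesS >= trials$accessStartS[i] & lickTimesS < trials$accessEndS[i]
    out[hit] <- trials$trial[i]
  }
  out
}
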