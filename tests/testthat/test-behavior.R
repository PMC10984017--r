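# Rank scoring, bout segmentation, microstructure and contrasts.

test_that("percent wins equals the brute-force tally", {
  allWin <- TournamentRecord(data.frame(
    day = rep(1:3, each = 3), mouseA = "m1",
    mouseB = rep(c("m2", "m3", "m4"), 3), winner = "m1"))
  expect_equal(percentWins(allWin, "m1"), 100)
  expect_equal(percentWins(allWin, "m2"), 0)
  expect_error(percentWins(allWin, "m9"), "does not appear")
  # random round-robins vs exhaustive count
  for (s in 1:20) {
    rec <- genTournament(4, skillSpread = 1, seed = s)$record
    tr <- tournamentTrials(rec)
    for (m in paste0("m", 1:4)) {
      inT <- tr$mouseA == m | tr$mouseB == m
      expect_equal(percentWins(rec, m), 100 * sum(tr$winner == m) / sum(inT))
    }
  }
})

test_that("rank assignment is a monotone permutation with deterministic ties", {
  for (s in 1:50) {
    rec <- genTournament(4, skillSpread = 0.5, seed = s)$record
    rt <- assignRanks(rec)
    expect_setequal(rt$rank, 1:4)
    expect_true(all(diff(rt$percentWins) <= 1e-12))  # sorted by rank
  }
  # two mice with identical percent wins and head-to-head: id breaks the tie
  tie <- TournamentRecord(data.frame(
    day = c(1, 1), mouseA = c("a", "b"), mouseB = c("b", "a"),
    winner = c("a", "b")))
  rt <- assignRanks(tie)
  expect_equal(rt$mouse[rt$rank == 1], "a")
  expect_error(assignRanks(TournamentRecord(data.frame(
    day = 1, mouseA = "a", mouseB = "b", winner = "a")[0, ])), "two mice")
})

test_that("bout segmentation matches the scan oracle and conserves licks", {
  s <- LickStream(c(0.0, 0.1, 0.2, 5.0, 5.1, 5.2))
  b <- segmentBouts(s, iliThresholdS = 1.0, minLicks = 3)
  expect_equal(nrow(b), 2)
  expect_equal(b$nLicks, c(3L, 3L))
  expect_equal(nrow(segmentBouts(LickStream(numeric(0)))), 0)
  set.seed(41)
  for (i in 1:200) {
    times <- randomLickTimes(sample(0:60, 1))
    thr <- runif(1, 0.2, 2); ml <- sample(1:4, 1)
    got <- segmentBouts(LickStream(times), thr, ml)
    want <- oracleBouts(times, thr, ml)
    expect_equal(got$startS, want$startS)
    expect_equal(got$endS, want$endS)
    expect_equal(got$nLicks, want$nLicks)
    # lick conservation: bout licks + discarded-run licks = total
    runs <- oracleBouts(times, thr, 1L)
    expect_equal(sum(runs$nLicks), length(times))
    expect_equal(sum(got$nLicks) + sum(runs$nLicks[runs$nLicks < ml]),
                 length(times))
  }
})

test_that("microstructure summaries are consistent with ground truth", {
  s <- LickStream(c(0, .1, .2, 5, 5.1, 5.2))
  b <- segmentBouts(s)
  ms <- microstructureSummary(b, s)
  expect_equal(ms$totalLicks, 6)
  expect_equal(ms$nBouts, 2)
  expect_equal(ms$meanLicksPerBout, 3)
  ms0 <- microstructureSummary(segmentBouts(LickStream(numeric(0))),
                               LickStream(numeric(0)))
  expect_equal(ms0$nBouts, 0)
  expect_true(is.na(ms0$meanLicksPerBout))
  # generator ground truth is recovered exactly at the default criterion
  g <- genLickStream(900, boutRateMin = 3, seed = 17)
  b <- segmentBouts(g$stream)
  expect_equal(b$nLicks, g$truth$nLicks)
  expect_equal(b$startS, g$truth$startS)
})

test_that("condition contrast handles degenerate and paired designs", {
  d0 <- expand.grid(mouse = paste0("m", 1:8), condition = c("pre_SI", "SI"))
  d0$rank <- rep(rep(1:2, each = 4), 2)
  d0$totalLicks <- 5
  r0 <- conditionContrast(d0)
  expect_true(all(r0$anova$F == 0))
  # one rank level: condition F equals the paired t statistic squared
  d1 <- d0[d0$rank == 1, ]
  set.seed(7); d1$totalLicks <- rnorm(8) + ifelse(d1$condition == "SI", 1, 0)
  r1 <- conditionContrast(d1)
  tt <- t.test(d1$totalLicks[d1$condition == "SI"],
               d1$totalLicks[d1$condition == "pre_SI"], paired = TRUE)
  f <- r1$anova$F[r1$anova$term == "condition"]
  expect_equal(f, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(r1$design, "within")
  # empty cell errors informatively
  dBad <- d0[!(d0$rank == 2 & d0$condition == "SI"), ]
  expect_error(conditionContrast(dBad), "degrees of freedom")
})

test_that("cue trials partition the session and licks map uniquely", {
  tt <- trialsFromCues(c(0, 120), 60)
  expect_equal(nrow(tt), 2)
  expect_true(all(tt$accessEndS[-2] <= tt$accessStartS[-1]))
  tt2 <- trialsFromCues(c(0, 100, 200, 300), 60,
                        stimulatedFlags = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(mean(tt2$stimulated), 0.5)
  expect_error(trialsFromCues(c(0, 30), 60), "overlap")
  set.seed(13)
  for (i in 1:20) {
    onsets <- cumsum(runif(10, 70, 130))
    tr <- trialsFromCues(onsets, 60)
    licks <- runif(200, 0, max(onsets) + 100)
    idx <- licksToTrials(licks, tr)
    # each lick inside a window maps to exactly the covering trial
    for (j in which(!is.na(idx))) {
      expect_true(licks[j] >= tr$accessStartS[idx[j]] &&
                    licks[j] < tr$accessEndS[idx[j]])
    }
    inAny <- colSums(sapply(licks, function(l)
      l >= tr$accessStartS & l < tr$accessEndS))
    expect_true(all(inAny <= 1))
    expect_equal(sum(!is.na(idx)), sum(inAny))
  }
})
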