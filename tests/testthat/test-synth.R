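# Synthetic-cohort generators: determinism, planted structure, guards.

test_that("tournament outcomes follow latent skill and are reproducible", {
  # infinite skill spread: wins forced by skill order
  t1 <- genTournament(4, skillSpread = Inf, seed = 3)
  pw <- vapply(t1$truth$mouse, function(m) percentWins(t1$record, m), 0)
  expect_true(all(diff(pw) < 0))
  expect_equal(unname(pw[1]), 100)
  # zero spread: coin flips, percent wins near 50 over many trials
  t0 <- genTournament(2, skillSpread = 0, days = 5000, seed = 4)
  p <- percentWins(t0$record, "m1") / 100
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 10000))
  # determinism and schedule: every ordered pair meets once per day
  ta <- genTournament(4, seed = 11)
  tb <- genTournament(4, seed = 11)
  expect_identical(tournamentTrials(ta$record), tournamentTrials(tb$record))
  tr <- tournamentTrials(ta$record)
  expect_equal(nrow(tr), 3 * 4 * 3)  # 3 days x 12 ordered pairs
  expect_true(all(table(tr$day, paste(tr$mouseA, tr$mouseB)) == 1))
  expect_error(genTournament(1), "at least two")
})

test_that("lick-stream generator plants unambiguous bouts", {
  expect_equal(length(lickTimes(genLickStream(600, boutRateMin = 0,
                                              seed = 1)$stream)), 0)
  g <- genLickStream(600, nBouts = 5, fixedLicksPerBout = 10,
                     iliJitterSd = 0, seed = 2)
  expect_equal(length(lickTimes(g$stream)), 50)
  expect_equal(g$truth$nLicks, rep(10L, 5))
  # between-bout gaps respect the declared floor
  b <- g$truth
  expect_true(all(b$startS[-1] - b$endS[-5] >= g$gapFloorS - 1e-9))
  # Poisson bout count: mean over 100 seeds within 3 sigma of expectation
  lambda <- 2 * 600 / 60
  counts <- vapply(1:100, function(s)
    nrow(genLickStream(600, boutRateMin = 2, seed = s)$truth), 0)
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 100))
  expect_error(genLickStream(600, withinBoutIliS = 1.5, gapFloorS = 1),
               "overlapping-bout")
  expect_identical(lickTimes(genLickStream(300, seed = 9)$stream),
                   lickTimes(genLickStream(300, seed = 9)$stream))
})

test_that("pose generator plants detectable interaction episodes", {
  # no episodes -> detector finds nothing
  p0 <- genPoseSession(30, 30, seed = 5)
  ev0 <- detectInteraction(headBodyDistance(p0$session),
                           approachAngle(p0$session), fps = 30)
  expect_equal(interactionTime(ev0), 0)
  # one 10 s episode at 30 fps -> exactly 300 ground-truth frames
  p1 <- genPoseSession(60, 30, data.frame(startS = 10, stopS = 20), seed = 6)
  expect_equal(sum(p1$truth$interactingFrames), 300)
  # generated geometry satisfies the frame rule exactly on episode frames
  mask <- interactionFrameMask(headBodyDistance(p1$session),
                               approachAngle(p1$session))
  expect_identical(mask, p1$truth$interactingFrames)
  # keypoints stay inside the arena
  expect_true(all(p1$session@intruderBodyXy >= 0 &
                    p1$session@intruderBodyXy <= 600))
  expect_error(genPoseSession(60, 30, data.frame(startS = 50, stopS = 70)),
               "inside the session")
  expect_error(genPoseSession(60, 30, data.frame(startS = c(1, 5),
                                                 stopS = c(6, 10))),
               "non-overlapping")
})

test_that("calcium generator plants exact event-locked transients", {
  ev <- seq(20, 200, by = 20)
  cp <- genCalciumPopulation(10, ev, fracExcited = 0.5, fracInhibited = 0.5,
                             amplitudeZ = 3, noiseSd = 0, seed = 7)
  exc <- which(cp$truth$class == "excited")
  evIdx <- round(ev * 20) + 1  # frame at each event time (fps 20)
  for (i in exc)
    expect_equal(cp$traces[i, evIdx], rep(3, length(ev)), tolerance = 1e-6,
                 ignore_attr = TRUE)
  inh <- which(cp$truth$class == "inhibited")
  expect_equal(unname(cp$traces[inh[1], evIdx[1]]), -3, tolerance = 1e-6)
  expect_error(genCalciumPopulation(10, ev, fracExcited = 0.7,
                                    fracInhibited = 0.6),
               "fractions exceed 1")
  a <- genCalciumPopulation(5, ev, seed = 8)
  b <- genCalciumPopulation(5, ev, seed = 8)
  expect_identical(a$traces, b$traces)
})

test_that("identity-map generator hits the requested co-registration rate", {
  m1 <- genIdentityMap(3, 20, 1, seed = 1)
  expect_equal(as.numeric(coregistrationRate(m1$map)), 1)
  m0 <- genIdentityMap(3, 20, 0, seed = 2)
  expect_equal(as.numeric(coregistrationRate(m0$map)), 0)
  m3 <- genIdentityMap(4, 200, 0.3, seed = 3)
  nSpan <- sum(m3$truth$coregistered)
  expect_lt(abs(nSpan - 60), 3 * sqrt(200 * 0.3 * 0.7))
  # every session has exactly the requested neuron count
  expect_true(all(table(identityRows(m3$map)$session) == 200))
  expect_error(genIdentityMap(4, 10, 1.2), "0, 1")
})

test_that("cohort generator recovers planted rank structure end to end", {
  cfg <- cohortConfig(nCages = 2, sessionMin = 20, seed = 33)
  co <- genCohort(cfg)
  s <- cohortSummaries(co)
  # one summary row per mouse x condition x spout, each with ground truth
  expect_equal(nrow(s), 8 * 2 * 2)
  alc <- s[s$spout == "alcohol", ]
  # assigned ranks recover true ranks at the default skill spread
  expect_gt(cor(alc$rank, alc$trueRank), 0.8)
  # isolation adds licks
  expect_gt(mean(alc$totalLicks[alc$condition == "SI"]),
            mean(alc$totalLicks[alc$condition == "pre_SI"]))
  expect_error(cohortConfig(nCages = 0), "counts")
})
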