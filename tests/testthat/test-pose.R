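# Pose geometry, contact rule, and invariances.

mkSession <- function(head, body, intr, fps = 30) {
  PoseSession(fps, head, body, intr)
}

test_that("head-body distance is plain Euclidean geometry", {
  s <- mkSession(rbind(c(0, 0), c(1, 1)), rbind(c(-1, 0), c(0, 1)),
                 rbind(c(3, 4), c(1, 1)))
  expect_equal(headBodyDistance(s), c(5, 0))
  set.seed(3)
  h <- matrix(runif(40, 0, 100), ncol = 2)
  b <- h + matrix(rnorm(40), ncol = 2)
  i <- matrix(runif(40, 0, 100), ncol = 2)
  d <- headBodyDistance(mkSession(h, b, i))
  for (k in 1:20)
    expect_equal(d[k], sqrt(sum((h[k, ] - i[k, ])^2)))
})

test_that("approach angle matches an independent atan2 oracle", {
  # intruder dead ahead -> 0; dead behind -> 180
  s <- mkSession(rbind(c(1, 0), c(1, 0)), rbind(c(0, 0), c(0, 0)),
                 rbind(c(5, 0), c(-3, 0)))
  expect_equal(approachAngle(s), c(0, 180))
  set.seed(4)
  h <- matrix(runif(60, 0, 50), ncol = 2)
  b <- h + matrix(rnorm(60, 0, 5), ncol = 2)
  i <- matrix(runif(60, 0, 50), ncol = 2)
  got <- approachAngle(mkSession(h, b, i))
  want <- oracleAngle(h, b, i)
  expect_equal(got, want, tolerance = 1e-9)
  # degenerate heading is masked, not an error
  s2 <- mkSession(rbind(c(1, 1)), rbind(c(1, 1)), rbind(c(5, 5)))
  expect_true(is.na(approachAngle(s2)))
})

test_that("contact rule thresholds are inclusive and post-processing sane", {
  n <- 90
  ev <- detectInteraction(rep(50, n), rep(100, n), fps = 30)
  expect_equal(nrow(eventIntervals(ev)), 1)
  expect_equal(interactionTime(ev), 3)
  expect_equal(interactionTime(detectInteraction(rep(61, n), rep(100, n),
                                                 fps = 30)), 0)
  # boundary: exactly at threshold counts
  expect_equal(interactionTime(detectInteraction(rep(60, n), rep(135, n),
                                                 fps = 30,
                                                 minDurS = 0)), 3)
  # planted episodes recovered within one frame at each boundary
  p <- genPoseSession(60, 30, data.frame(startS = c(10, 40),
                                         stopS = c(20, 45)), seed = 12)
  ev <- detectInteraction(headBodyDistance(p$session),
                          approachAngle(p$session), fps = 30)
  iv <- eventIntervals(ev)
  expect_equal(nrow(iv), 2)
  expect_equal(iv$startS, c(10, 40), tolerance = 1 / 30 + 1e-9)
  expect_equal(iv$endS, c(20, 45), tolerance = 1 / 30 + 1e-9)
  expect_error(detectInteraction(rep(1, 5), rep(1, 5), 30,
                                 distThreshPx = -1), "non-negative")
})

test_that("interval output equals the frame-rule oracle before smoothing", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(50:300, 1)
    d <- runif(n, 30, 90)          # straddles the 60 px threshold
    a <- runif(n, 60, 180)
    d[sample(n, 5)] <- NA          # tracking dropouts break runs
    ev <- detectInteraction(d, a, fps = 20, minDurS = 0, mergeGapS = 0)
    mask <- oracleFrameRule(d, a, 60, 135)
    # reconstruct the mask from intervals and compare exactly
    got <- rep(FALSE, n)
    iv <- eventIntervals(ev)
    for (k in seq_len(nrow(iv))) {
      got[(round(iv$startS[k] * 20) + 1):round(iv$endS[k] * 20)] <- TRUE
    }
    expect_identical(got, mask)
    expect_equal(interactionTime(ev), sum(mask) / 20)
  }
})

test_that("interaction time sums intervals and detection is monotone", {
  expect_equal(interactionTime(EventSeries()), 0)
  expect_equal(interactionTime(EventSeries(data.frame(
    startS = c(0, 20), endS = c(10, 25)))), 15)
  set.seed(8)
  d <- runif(400, 30, 90); a <- runif(400, 60, 180)
  base <- interactionTime(detectInteraction(d, a, fps = 20))
  expect_gte(interactionTime(detectInteraction(d, a, fps = 20,
                                               distThreshPx = 80)), base)
  expect_gte(interactionTime(detectInteraction(d, a, fps = 20,
                                               angleThreshDeg = 170)), base)
})

test_that("geometry is invariant under global rotation and translation", {
  p <- genPoseSession(30, 30, data.frame(startS = 5, stopS = 15), seed = 31)
  s <- p$session
  th <- 0.83; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(-312.5, 97.2)
  tf <- function(m) sweep(m %*% t(R), 2, shift, "+")
  s2 <- PoseSession(30, tf(s@residentHeadXy), tf(s@residentBodyXy),
                    tf(s@intruderBodyXy))
  expect_equal(approachAngle(s2), approachAngle(s), tolerance = 1e-9)
  expect_equal(headBodyDistance(s2), headBodyDistance(s), tolerance = 1e-9)
  t1 <- interactionTime(detectInteraction(headBodyDistance(s),
                                          approachAngle(s), fps = 30))
  t2 <- interactionTime(detectInteraction(headBodyDistance(s2),
                                          approachAngle(s2), fps = 30))
  expect_equal(t1, t2)
})
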