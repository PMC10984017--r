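# Peri-event alignment, Z-scoring, classification, clustering, enrichment.

test_that("alignment resamples traces into peri-event bins correctly", {
  fps <- 20
  ft <- (0:1999) / fps
  # constant trace: every bin equals the constant
  tr <- matrix(5, 1, length(ft), dimnames = list("n1", NULL))
  te <- alignEvents(tr, ft, c(30, 50), binWidthS = 0.5)
  expect_true(all(tensorValues(te) == 5))
  # planted transient at the event: peak lands in the first response bin
  tr2 <- matrix(0, 1, length(ft), dimnames = list("n1", NULL))
  idx <- which(ft >= 40)
  tr2[1, idx] <- 3 * exp(-(ft[idx] - 40))
  te2 <- alignEvents(tr2, ft, 40, binWidthS = 0.25)
  prof <- tensorValues(te2)[1, 1, ]
  expect_equal(which.max(prof), which(binCenters(te2) > 0)[1])
  # edge events dropped with a logged count
  te3 <- alignEvents(tr, ft, c(2, 30, 98), binWidthS = 0.5)
  expect_equal(attr(te3, "droppedTrials"), 2)
  expect_equal(nTrials(te3), 1)
  expect_error(alignEvents(tr, ft, c(1, 99.9), binWidthS = 0.5),
               "no usable trials")
  # random events vs the direct indexing oracle
  set.seed(15)
  trR <- matrix(rnorm(2 * length(ft)), 2, length(ft),
                dimnames = list(c("a", "b"), NULL))
  evs <- runif(5, 10, 90)
  teR <- alignEvents(trR, ft, evs, binWidthS = 0.25)
  for (k in seq_along(evs)) {
    for (n in 1:2) {
      expect_equal(tensorValues(teR)[n, k, ],
                   oracleAlign(trR[n, ], ft, evs[k], teR@binEdges))
    }
  }
})

test_that("baseline Z-scoring uses pooled sample statistics", {
  # baseline {1, 3} across two trials (mu = 2, sample sd = sqrt(2));
  # response value 4 -> Z = 2 / sqrt(2)
  v <- array(0, c(1, 2, 2))
  v[1, , 1] <- c(1, 3)   # baseline bin, two trials
  v[1, , 2] <- c(4, 4)   # response bin
  te <- PeriEventTensor(v, c(-1, 0, 1), baselineWindow = c(-1, 0),
                        responseWindow = c(0, 1))
  z <- zscoreBaseline(te)
  expect_equal(tensorValues(z)[1, 1, 2], 2 / sqrt(2), tolerance = 1e-12)
  expect_equal(mean(tensorValues(z)[1, , 1]), 0, tolerance = 1e-12)
  # affine-transformed traces give identical Z output
  v2 <- 3.7 * v - 11
  z2 <- zscoreBaseline(PeriEventTensor(v2, c(-1, 0, 1),
                                       baselineWindow = c(-1, 0),
                                       responseWindow = c(0, 1)))
  expect_equal(tensorValues(z2), tensorValues(z), tolerance = 1e-9)
  # degenerate baselines are excluded, all-degenerate input errors
  vD <- array(1, c(2, 3, 2)); vD[2, , 1] <- c(1, 2, 3)
  teD <- PeriEventTensor(vD, c(-1, 0, 1), baselineWindow = c(-1, 0),
                         responseWindow = c(0, 1))
  zD <- zscoreBaseline(teD)
  expect_equal(nNeurons(zD), 1)
  expect_equal(attr(zD, "degenerateNeurons"), "n1")
  vC <- array(2, c(1, 3, 2))
  expect_error(zscoreBaseline(PeriEventTensor(vC, c(-1, 0, 1),
                                              baselineWindow = c(-1, 0),
                                              responseWindow = c(0, 1))),
               "degenerate")
})

test_that("classification needs both significance and magnitude", {
  # planted strong positive offset -> excited; negative -> inhibited
  up <- makeTensor(3, 20, offset = 2, noise = 0.3, seed = 5)
  labUp <- classifyResponses(up)
  expect_true(all(labUp$label == "excited"))
  dn <- makeTensor(3, 20, offset = -2, noise = 0.3, seed = 6)
  expect_true(all(classifyResponses(dn)$label == "inhibited"))
  # too few trials: labelled none with a reason
  few <- makeTensor(2, 3, offset = 2, noise = 0.1, seed = 7)
  labFew <- classifyResponses(few)
  expect_true(all(labFew$label == "none"))
  expect_match(labFew$reason[1], "usable trials")
  # every flagged neuron satisfies both criteria (mutual exclusivity of
  # the label rule: p below alpha AND magnitude past the threshold)
  lab <- classifyResponses(makeTensor(50, 10, offset = 0, seed = 8))
  flagged <- lab$label != "none"
  expect_true(all(abs(lab$zStat[flagged]) >= 1.98))
  expect_true(all(lab$pValue[flagged] <= 0.05))
})

test_that("population comparison detects planted condition offsets", {
  a <- makeTensor(30, 10, offset = 0, seed = 21)
  r0 <- populationMeanResponse(a, a)
  expect_true(all(r0$anova$F[r0$anova$term != "time"] == 0))
  # all-zero tensor -> flat zero time course
  z <- makeTensor(5, 5, seed = 1)
  z@values[] <- 0
  rz <- populationMeanResponse(z, z)
  expect_true(all(rz$timecourse$mean == 0))
  # planted +1 Z condition offset is detected across seeds
  hits <- vapply(1:10, function(s) {
    x <- makeTensor(100, 10, offset = 0, seed = 100 + s)
    y <- makeTensor(100, 10, offset = 1, seed = 200 + s)
    r <- populationMeanResponse(x, y)
    r$anova$p[r$anova$term == "condition"] < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  expect_error(populationMeanResponse(a, makeTensor(3, 4, seed = 2,
                                                    nTrials = 4)), NA)
})

test_that("functional clustering recovers planted motifs deterministically", {
  set.seed(31)
  tpts <- seq(-2, 2, by = 0.25)[-1]
  early <- exp(-pmax(tpts, 0) * 2) * (tpts > 0)      # early peak
  dip <- -1 * (tpts > 0.5)                           # sustained dip
  m <- rbind(
    t(replicate(20, early * 3 + rnorm(length(tpts), 0, 0.2))),
    t(replicate(20, dip * 2 + rnorm(length(tpts), 0, 0.2))))
  rownames(m) <- paste0("n", 1:40)
  cl <- clusterFunctional(m, k = 2)
  ids <- clusterAssignments(cl)
  # planted motifs recovered (cluster 1 = strongest peak = early group)
  expect_gte(mean(ids[1:20] == 1), 0.95)
  expect_gte(mean(ids[21:40] == 2), 0.95)
  # permuted neuron order yields the identical partition
  perm <- sample(40)
  cl2 <- clusterFunctional(m[perm, ], k = 2)
  expect_identical(clusterAssignments(cl2)[rownames(m)], ids)
  # all-identical time courses: zero within-cluster variance at any k
  mm <- matrix(rep(early, 10), nrow = 10, byrow = TRUE,
               dimnames = list(paste0("n", 1:10), NULL))
  clI <- clusterFunctional(mm, k = 2)
  expect_equal(unname(clI@clusterMeans[1, ]), early)
  expect_error(clusterFunctional(m, k = 1), "at least 2")
})

test_that("cluster enrichment normalizes by group size", {
  set.seed(32)
  m <- matrix(rnorm(40 * 16), 40, dimnames = list(paste0("n", 1:40), NULL))
  cl <- clusterFunctional(m, k = 3)
  # identically distributed groups (duplicate each neuron's label evenly)
  gEven <- setNames(rep(c("bla", "proj"), 20), paste0("n", 1:40))
  # craft a clustering where both groups populate clusters identically:
  ids <- clusterAssignments(cl)
  gMirror <- setNames(ifelse(seq_len(40) %% 2 == 0, "bla", "proj"),
                      names(ids))
  enr <- clusterEnrichment(cl, gMirror)
  expect_equal(rowSums(enr$normalizedProportions),
               rep(1, 3), ignore_attr = TRUE)
  expect_equal(colSums(enr$perGroupClusterProps),
               rep(1, 2), ignore_attr = TRUE)
  # chi-square equals the textbook formula on the same table
  expect_equal(enr$chi2, oracleChi2(unclass(enr$table)), tolerance = 1e-9)
  # a cluster with only one group is fully enriched
  cl1 <- cl
  gOnly <- gMirror
  gOnly[names(ids)[ids == 1]] <- "bla"
  enr1 <- clusterEnrichment(cl1, gOnly)
  expect_equal(unname(enr1$normalizedProportions[1, "bla"]), 1)
  expect_error(clusterEnrichment(cl, gMirror[-1]), "group label")
})
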