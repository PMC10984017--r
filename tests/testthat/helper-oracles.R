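# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive scalar loops, not the package's code paths.

# O(n) scan: group licks into runs by inter-lick interval, drop short runs.
oracleBouts <- function(times, thr, minLicks) {
  if (!length(times)) {
    return(data.frame(startS = numeric(0), endS = numeric(0),
                      nLicks = integer(0)))
  }
  starts <- numeric(0); ends <- numeric(0); counts <- integer(0)
  runStart <- times[1]; n <- 1L
  for (i in seq_along(times)[-1]) {
    if (times[i] - times[i - 1] <= thr) {
      n <- n + 1L
    } else {
      if (n >= minLicks) {
        starts <- c(starts, runStart); ends <- c(ends, times[i - 1])
        counts <- c(counts, n)
      }
      runStart <- times[i]; n <- 1L
    }
  }
  if (n >= minLicks) {
    starts <- c(starts, runStart); ends <- c(ends, times[length(times)])
    counts <- c(counts, n)
  }
  data.frame(startS = starts, endS = ends, nLicks = as.integer(counts))
}

# Per-frame boolean contact rule, scalar loop.
oracleFrameRule <- function(d, a, dt, at) {
  out <- logical(length(d))
  for (i in seq_along(d)) {
    out[i] <- !is.na(d[i]) && !is.na(a[i]) && d[i] <= dt && a[i] <= at
  }
  out
}

# Angle between body->head and head->intruder via atan2 difference.
oracleAngle <- function(head, body, intr) {
  n <- nrow(head)
  out <- numeric(n)
  for (i in seq_len(n)) {
    a1 <- atan2(head[i, 2] - body[i, 2], head[i, 1] - body[i, 1])
    a2 <- atan2(intr[i, 2] - head[i, 2], intr[i, 1] - head[i, 1])
    da <- abs(a1 - a2) %% (2 * pi)
    if (da > pi) da <- 2 * pi - da
    out[i] <- da * 180 / pi
  }
  out
}

# Direct per-bin indexing oracle for peri-event alignment of one trace.
oracleAlign <- function(trace, frameTimes, event, edges) {
  nb <- length(edges) - 1L
  out <- numeric(nb)
  for (b in seq_len(nb)) {
    sel <- which(frameTimes - event >= edges[b] &
                   frameTimes - event < edges[b + 1])
    out[b] <- if (length(sel)) mean(trace[sel]) else NA_real_
  }
  out
}

# Textbook chi-square on a 2x2 table, no correction.
oracleChi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Random strictly-sorted lick times with mixed short/long gaps.
randomLickTimes <- function(n, maxGap = 3) {
  if (n == 0) return(numeric(0))
  cumsum(runif(n, 0.01, maxGap))
}

# Small Z-scored tensor with a planted per-neuron response offset.
makeTensor <- function(nNeurons = 5, nTrials = 8, offset = 0, noise = 1,
                       seed = 1) {
  withr::with_seed(seed, {
    edges <- seq(-2, 2, by = 0.5)
    nb <- length(edges) - 1
    centers <- (edges[-1] + edges[-nb - 1]) / 2
    v <- array(rnorm(nNeurons * nTrials * nb, 0, noise),
               c(nNeurons, nTrials, nb))
    v[, , centers > 0] <- v[, , centers > 0] + offset
    PeriEventTensor(v, edges, baselineWindow = c(-2, 0),
                    responseWindow = c(0, 2), zScored = TRUE)
  })
}
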