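#' @include AllClasses.R AllGenerics.R utils.R
NULL

# ---------------------------------------------------------------------------
# Peri-event alignment and baseline normalization
# ---------------------------------------------------------------------------

#' Align calcium traces around event times
#'
#' Excerpts every trace around each event and resamples it into fixed
#' peri-event time bins spanning the baseline window through the end of
#' the response window. Bin `b` covers relative time
#' `[edge_b, edge_{b+1})` and takes the mean of the trace samples falling
#' in it. Events whose window is not fully covered by the recording are
#' dropped and their count recorded in the `"droppedTrials"` attribute.
#'
#' @param traces neurons x frames numeric matrix (rownames = neuron ids).
#' @param frameTimes frame timestamps (s), strictly increasing, one per
#'   column of `traces`.
#' @param eventTimes event times (s).
#' @param baselineWindow,responseWindow two-element windows (s) relative to
#'   the event; baseline must precede the response.
#' @param binWidthS peri-event bin width (s); must tile the full span.
#' @param eventClass label stored on the tensor.
#' @return A raw (non-Z-scored) [PeriEventTensor-class].
#' @export
alignEvents <- function(traces, frameTimes, eventTimes,
                        baselineWindow = c(-5, 0), responseWindow = c(0, 5),
                        binWidthS = 0.25, eventClass = "event") {
  stopifnot(is.matrix(traces), ncol(traces) == length(frameTimes),
            binWidthS > 0)
  if (is.unsorted(frameTimes, strictly = TRUE))
    stop("frame times must be strictly increasing")
  span <- c(baselineWindow[1], responseWindow[2])
  nBins <- round(diff(span) / binWidthS)
  if (abs(nBins * binWidthS - diff(span)) > 1e-9)
    stop("bin width must tile the baseline-through-response span exactly")
  edges <- span[1] + binWidthS * (0:nBins)
  tMin <- frameTimes[1]; tMax <- frameTimes[length(frameTimes)]
  usable <- eventTimes + span[1] >= tMin & eventTimes + span[2] <= tMax
  dropped <- sum(!usable)
  eventTimes <- eventTimes[usable]
  if (!length(eventTimes))
    stop("no usable trials: all events overlap the recording edges")
  vals <- array(NA_real_, dim = c(nrow(traces), length(eventTimes), nBins))
  for (k in seq_along(eventTimes)) {
    rel <- frameTimes - eventTimes[k]
    sel <- which(rel >= span[1] & rel < span[2])
    bin <- floor((rel[sel] - span[1]) / binWidthS) + 1L
    bin <- pmin(bin, nBins)
    cnt <- tabulate(bin, nBins)
    M <- matrix(0, length(sel), nBins)
    M[cbind(seq_along(sel), bin)] <- 1
    M <- sweep(M, 2, pmax(cnt, 1L), "/")
    vals[, k, ] <- traces[, sel, drop = FALSE] %*% M
    vals[, k, cnt == 0L] <- NA_real_
  }
  out <- PeriEventTensor(vals, edges, eventClass = eventClass,
                         neuronIds = rownames(traces),
                         baselineWindow = baselineWindow,
                         responseWindow = responseWindow, zScored = FALSE)
  attr(out, "droppedTrials") <- dropped
  out
}

#' Baseline Z-score a peri-event tensor
#'
#' Per neuron, Z = (x - mu) / sd with mu and sd (sample SD) pooled over
#' all baseline bins across trials. Neurons with baseline SD below `eps`
#' are degenerate and excluded (ids recorded in the `"degenerateNeurons"`
#' attribute). The transform is invariant to per-neuron affine rescaling
#' of the raw traces.
#'
#' @param tensor a raw [PeriEventTensor-class].
#' @param eps degeneracy guard on the baseline SD (default 1e-6).
#' @return A Z-scored [PeriEventTensor-class].
#' @export
setMethod("zscoreBaseline", "PeriEventTensor", function(tensor, eps = 1e-6) {
  if (tensor@zScored) stop("tensor is already Z-scored")
  bb <- baselineBins(tensor)
  if (!any(bb)) stop("no baseline bins present")
  v <- tensor@values
  mu <- apply(v[, , bb, drop = FALSE], 1, mean, na.rm = TRUE)
  sd <- apply(v[, , bb, drop = FALSE], 1, stats::sd, na.rm = TRUE)
  keep <- is.finite(sd) & sd >= eps
  if (!any(keep)) stop("all neurons have degenerate (constant) baselines")
  z <- (v[keep, , , drop = FALSE] - mu[keep]) / sd[keep]
  out <- PeriEventTensor(z, tensor@binEdges, tensor@eventClass,
                         tensor@neuronIds[keep], tensor@baselineWindow,
                         tensor@responseWindow, zScored = TRUE)
  attr(out, "degenerateNeurons") <- tensor@neuronIds[!keep]
  out
})

# ---------------------------------------------------------------------------
# Responsive-neuron classification
# ---------------------------------------------------------------------------

#' Classify neurons as excited, inhibited, or unresponsive
#'
#' Per neuron, the per-trial response-minus-baseline difference (in Z
#' units) is tested against zero with a Wilcoxon signed-rank test, and the
#' standardized mean response `zStat = mean(d) / (sd(d)/sqrt(n))` is
#' compared against `±zThresh`. A neuron is labelled excited only if
#' `p <= alpha` AND `zStat >= zThresh`, inhibited only if `p <= alpha` AND
#' `zStat <= -zThresh`; otherwise none. Neurons with fewer than
#' `minTrials` trials are labelled none with a recorded reason.
#'
#' @param tensor a Z-scored [PeriEventTensor-class].
#' @param alpha significance level (default 0.05).
#' @param zThresh magnitude criterion on the standardized mean response
#'   (default 1.98, the two-sided 5% normal critical value).
#' @param minTrials minimum trials required (default 5).
#' @return data.frame (`neuronId`, `eventClass`, `label`, `statistic`,
#'   `pValue`, `meanRespZ` raw mean response Z, `zStat`, `reason`).
#' @export
setMethod("classifyResponses", "PeriEventTensor",
          function(tensor, alpha = 0.05, zThresh = 1.98, minTrials = 5L) {
  if (!tensor@zScored) stop("classifyResponses needs a Z-scored tensor")
  rb <- responseBins(tensor); bb <- baselineBins(tensor)
  n <- nNeurons(tensor); nt <- nTrials(tensor)
  out <- data.frame(neuronId = tensor@neuronIds,
                    eventClass = tensor@eventClass, label = "none",
                    statistic = NA_real_, pValue = NA_real_,
                    meanRespZ = NA_real_, zStat = NA_real_,
                    reason = NA_character_)
  for (i in seq_len(n)) {
    d <- apply(tensor@values[i, , rb, drop = FALSE], 2, mean, na.rm = TRUE) -
      apply(tensor@values[i, , bb, drop = FALSE], 2, mean, na.rm = TRUE)
    d <- d[is.finite(d)]
    if (length(d) < minTrials) {
      out$reason[i] <- sprintf("only %d usable trials (< %d)", length(d),
                               minTrials)
      next
    }
    wt <- suppressWarnings(stats::wilcox.test(d, mu = 0))
    sdd <- stats::sd(d)
    z <- if (sdd > 0) mean(d) / (sdd / sqrt(length(d))) else
      sign(mean(d)) * Inf
    out$statistic[i] <- unname(wt$statistic)
    out$pValue[i] <- wt$p.value
    out$meanRespZ[i] <- mean(tensor@values[i, , rb], na.rm = TRUE)
    out$zStat[i] <- z
    if (is.finite(wt$p.value) && wt$p.value <= alpha) {
      if (z >= zThresh) out$label[i] <- "excited"
      else if (z <= -zThresh) out$label[i] <- "inhibited"
    }
  }
  out
})

# ---------------------------------------------------------------------------
# Population time courses and condition comparison
# ---------------------------------------------------------------------------

#' Population mean peri-event response and condition-by-time ANOVA
#'
#' Neuron-averaged time courses (mean +/- SEM across neurons of the
#' trial-averaged response) for two tensors, and a two-factor
#' condition x time-bin ANOVA on the per-neuron per-bin trial means, the
#' population-level contrast used for isolation and stimulation effects.
#'
#' @param tensorA,tensorB Z-scored [PeriEventTensor-class] objects with
#'   identical binning.
#' @param labels condition labels for the two tensors.
#' @return list: `timecourse` (data.frame `condition`, `timeS`, `mean`,
#'   `sem`), `anova` (term, df, sumSq, F, p).
#' @export
populationMeanResponse <- function(tensorA, tensorB,
                                   labels = c("A", "B")) {
  if (length(tensorA@binEdges) != length(tensorB@binEdges) ||
      any(abs(tensorA@binEdges - tensorB@binEdges) > 1e-9))
    stop("tensors must share the same peri-event binning")
  perNeuron <- function(tensor) {
    apply(tensor@values, c(1, 3), mean, na.rm = TRUE)  # neurons x bins
  }
  tc <- function(m, label, centers) {
    data.frame(condition = label, timeS = centers,
               mean = colMeans(m, na.rm = TRUE),
               sem = apply(m, 2, sem), row.names = NULL)
  }
  mA <- perNeuron(tensorA); mB <- perNeuron(tensorB)
  centers <- binCenters(tensorA)
  timecourse <- rbind(tc(mA, labels[1], centers), tc(mB, labels[2], centers))
  long <- rbind(
    data.frame(value = as.vector(mA), condition = labels[1],
               time = factor(rep(centers, each = nrow(mA)))),
    data.frame(value = as.vector(mB), condition = labels[2],
               time = factor(rep(centers, each = nrow(mB)))))
  long$condition <- factor(long$condition)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  fit <- stats::aov(value ~ condition * time, data = long)
  list(timecourse = timecourse, anova = flattenAov(fit))
}

# ---------------------------------------------------------------------------
# Hierarchical functional clustering and enrichment
# ---------------------------------------------------------------------------

#' Hierarchically cluster neural response time courses
#'
#' Agglomerative clustering (Ward linkage on correlation distance of
#' per-neuron standardized trial-averaged time courses) into `k`
#' functional clusters. Cluster ids are relabeled by descending peak of
#' the cluster-mean time course so cluster 1 always has the strongest
#' peak; the result is invariant to neuron order.
#'
#' @param x a Z-scored [PeriEventTensor-class], or a neurons x bins matrix
#'   of trial-averaged time courses (rownames = neuron ids).
#' @param k number of clusters (>= 2).
#' @return A [FunctionalClustering-class].
#' @export
clusterFunctional <- function(x, k = 9L) {
  if (is(x, "PeriEventTensor")) {
    m <- apply(x@values, c(1, 3), mean, na.rm = TRUE)
    rownames(m) <- x@neuronIds
    centers <- binCenters(x)
  } else {
    m <- as.matrix(x)
    if (is.null(rownames(m))) rownames(m) <- paste0("n", seq_len(nrow(m)))
    centers <- seq_len(ncol(m))
  }
  if (k < 2) stop("k must be at least 2")
  if (nrow(m) < k) stop("need at least k neurons to form k clusters")
  sdv <- apply(m, 1, stats::sd)
  ms <- (m - rowMeans(m)) / ifelse(sdv > 0, sdv, 1)
  cr <- suppressWarnings(stats::cor(t(ms)))
  cr[!is.finite(cr)] <- 0
  d <- stats::as.dist(1 - cr)
  tree <- stats::hclust(d, method = "ward.D2")
  raw <- stats::cutree(tree, k = k)
  means <- do.call(rbind, lapply(seq_len(k), function(c)
    colMeans(m[raw == c, , drop = FALSE])))
  ord <- order(-apply(means, 1, max))
  relabel <- match(seq_len(k), ord)
  ids <- relabel[raw]
  names(ids) <- rownames(m)
  sil <- if (k < nrow(m)) {
    mean(cluster::silhouette(ids, d)[, "sil_width"])
  } else NA_real_
  new("FunctionalClustering", clusterIds = as.integer(ids) |>
        stats::setNames(rownames(m)),
      tree = tree, clusterMeans = means[ord, , drop = FALSE],
      binCentersS = centers, silhouette = sil)
}

#' Group enrichment of functional clusters
#'
#' For each cluster `c` and group `g` the normalized proportion
#' `(n_cg / N_g) / sum_g' (n_cg' / N_g')` corrects for unequal numbers of
#' neurons recorded per group (0.5 everywhere means no enrichment for two
#' groups). A chi-square test of the cluster x group contingency table
#' tests whether cluster membership depends on group.
#'
#' @param clustering a [FunctionalClustering-class].
#' @param groups named character vector mapping every clustered neuron id
#'   to its group (e.g. non-specific vs projection-specific).
#' @return list: `normalizedProportions` (clusters x groups, rows sum to
#'   1), `perGroupClusterProps` (share of each group's neurons per
#'   cluster, columns sum to 1), `table` (counts), `chi2`, `df`, `p`.
#' @export
clusterEnrichment <- function(clustering, groups) {
  ids <- clustering@clusterIds
  if (!all(names(ids) %in% names(groups)))
    stop("every clustered neuron needs a group label")
  g <- factor(groups[names(ids)])
  if (any(table(g) == 0)) stop("empty group")
  k <- nrow(clustering@clusterMeans)
  tab <- table(cluster = factor(ids, levels = seq_len(k)), group = g)
  Ng <- table(g)
  perGroup <- sweep(unclass(tab), 2, as.numeric(Ng), "/")
  norm <- perGroup / pmax(rowSums(perGroup), .Machine$double.eps)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(normalizedProportions = norm, perGroupClusterProps = perGroup,
       table = tab, chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
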