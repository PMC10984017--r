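#' @include AllClasses.R utils.R
NULL

# ---------------------------------------------------------------------------
# Pseudo-simultaneous population construction
# ---------------------------------------------------------------------------

#' Whole-trace per-neuron Z-score
#'
#' Normalizes each trace by its own overall mean and sample SD. For
#' decoding features the normalization must be class-agnostic: Z-scoring
#' each event class against its own estimated baseline imprints a small
#' class-dependent offset per neuron (the estimate is shared by all of
#' that class's trials), which a classifier happily decodes on otherwise
#' chance-level data. A single whole-trace normalization per neuron
#' carries no class information.
#'
#' @param traces neurons x frames matrix.
#' @param eps degeneracy guard on the trace SD.
#' @return Matrix of the same shape in Z units; constant traces are left
#'   at zero.
#' @export
zscoreTraces <- function(traces, eps = 1e-6) {
  mu <- rowMeans(traces)
  sd <- apply(traces, 1, stats::sd)
  sd[!is.finite(sd) | sd < eps] <- 1
  (traces - mu) / sd
}

#' Per-neuron per-trial decoding features from a peri-event tensor
#'
#' Feature of a trial = mean activity in the feature window (default the
#' tensor's response window), optionally minus the same trial's mean
#' baseline activity (`baselineSubtract`), which removes slow drift
#' without introducing class-dependent normalization.
#'
#' @param tensor a [PeriEventTensor-class] (typically aligned from
#'   [zscoreTraces()] output when used for decoding).
#' @param featureWindow two-element window (s); default the response
#'   window.
#' @param baselineSubtract subtract the per-trial baseline mean
#'   (default FALSE).
#' @return list (one element per neuron, named by neuron id) of numeric
#'   per-trial feature vectors.
#' @export
tensorFeatures <- function(tensor, featureWindow = NULL,
                           baselineSubtract = FALSE) {
  if (is.null(featureWindow)) featureWindow <- tensor@responseWindow
  c <- binCenters(tensor)
  fb <- c >= featureWindow[1] & c < featureWindow[2]
  if (!any(fb)) stop("feature window contains no bins")
  bb <- baselineBins(tensor)
  out <- lapply(seq_len(nNeurons(tensor)), function(i) {
    f <- apply(tensor@values[i, , fb, drop = FALSE], 2, mean, na.rm = TRUE)
    if (baselineSubtract)
      f <- f - apply(tensor@values[i, , bb, drop = FALSE], 2, mean,
                     na.rm = TRUE)
    f
  })
  names(out) <- tensor@neuronIds
  out
}

#' Build a pseudo-simultaneous population dataset
#'
#' For each resample and each class, every eligible neuron contributes
#' `nTrialsPerClass` of its own trials drawn with replacement,
#' independently per neuron and per class; the draws are stacked into a
#' balanced pseudo-trial x neuron feature matrix. Trials never cross
#' neurons or animals: a pseudo-trial is an artificial conjunction of
#' independently sampled real trials.
#'
#' Cross-validation folds are fixed at build time and respect real-trial
#' identity: per resample, each neuron's real trials are partitioned into
#' `folds` disjoint subsets, and a pseudo-trial assigned to fold `f` draws
#' every neuron's feature only from that neuron's fold-`f` trials. A
#' held-out pseudo-trial therefore never reuses a real trial seen during
#' training, which keeps chance-level data at chance; resampling pseudo-
#' trials freely across folds instead leaks trial noise into the held-out
#' folds and inflates accuracy.
#'
#' Neurons with fewer than `minTrials` trials in any class are excluded
#' (count in the `"excludedNeurons"` attribute).
#'
#' @param featuresByClass named list (one element per class) of per-neuron
#'   feature lists as returned by [tensorFeatures()]; neuron names must
#'   match across classes.
#' @param nTrialsPerClass pseudo-trials per class per resample (default
#'   20); must be a multiple-friendly count of at least `folds`.
#' @param nResamples number of resamples (default 100).
#' @param minTrials minimum real trials per class for a neuron to be
#'   eligible (default 5; must be >= `folds` so every fold is non-empty).
#' @param folds cross-validation folds baked into the resamples
#'   (default 5).
#' @param provenance optional data.frame (`neuron`, `animal`, `group`).
#' @param seed integer seed.
#' @return A [PseudoPopulationDataset-class]; each resample carries
#'   `x`, `y` and the pseudo-trial fold assignment `fold`.
#' @export
buildPseudopopulation <- function(featuresByClass, nTrialsPerClass = 20L,
                                  nResamples = 100L, minTrials = 5L,
                                  folds = 5L, provenance = NULL, seed = 1L) {
  stopifnot(is.list(featuresByClass), length(featuresByClass) >= 2)
  if (minTrials < folds)
    stop("minTrials must be at least `folds` so every fold holds a trial")
  if (nTrialsPerClass < folds)
    stop("nTrialsPerClass must be at least `folds`")
  classes <- names(featuresByClass)
  neurons <- names(featuresByClass[[1]])
  if (!all(vapply(featuresByClass, function(f)
    identical(names(f), neurons), TRUE)))
    stop("neuron sets must match across classes")
  eligible <- vapply(neurons, function(n)
    all(vapply(featuresByClass, function(f)
      sum(is.finite(f[[n]])) >= minTrials, TRUE)), TRUE)
  excluded <- sum(!eligible)
  neurons <- neurons[eligible]
  if (!length(neurons)) stop("no eligible neurons after the trial-count filter")
  if (is.null(provenance))
    provenance <- data.frame(neuron = neurons, animal = NA_character_,
                             group = NA_character_)
  else provenance <- provenance[match(neurons, provenance$neuron), ,
                                drop = FALSE]
  # fold of pseudo-trial j within each class: dealt round-robin
  pseudoFold <- rep_len(seq_len(folds), nTrialsPerClass)
  resamples <- withSeed(seed, {
    lapply(seq_len(nResamples), function(r) {
      cols <- lapply(neurons, function(n) {
        unlist(lapply(classes, function(cl) {
          f <- featuresByClass[[cl]][[n]]
          f <- f[is.finite(f)]
          trialFold <- sample(rep_len(seq_len(folds), length(f)))
          vapply(pseudoFold, function(fd) {
            pool <- f[trialFold == fd]
            pool[sample.int(length(pool), 1L)]
          }, 0)
        }))
      })
      x <- do.call(cbind, cols)
      colnames(x) <- neurons
      list(x = x, y = factor(rep(classes, each = nTrialsPerClass),
                             levels = classes),
           fold = rep(pseudoFold, length(classes)))
    })
  })
  out <- new("PseudoPopulationDataset", resamples = resamples,
             provenance = provenance,
             nTrialsPerClass = as.integer(nTrialsPerClass),
             seed = as.integer(seed))
  attr(out, "excludedNeurons") <- excluded
  out
}

# ---------------------------------------------------------------------------
# SVM decoding with stratified cross-validation
# ---------------------------------------------------------------------------

# Linear SVM CV accuracy for one feature matrix with a fixed fold
# assignment; features are standardized with training-fold statistics only
# (no leakage into held-out folds).
cvAccuracy <- function(x, y, fold, cost = 1) {
  correct <- 0L
  for (f in sort(unique(fold))) {
    tr <- fold != f
    mu <- colMeans(x[tr, , drop = FALSE])
    sd <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sd[!is.finite(sd) | sd < 1e-12] <- 1
    xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sd, "/")
    xte <- sweep(sweep(x[!tr, , drop = FALSE], 2, mu), 2, sd, "/")
    fit <- e1071::svm(xtr, y[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
    correct <- correct + sum(stats::predict(fit, xte) == y[!tr])
  }
  correct / length(y)
}

#' Decode class labels from a pseudo-population dataset
#'
#' Linear support-vector-machine decoding with the stratified k-fold
#' cross-validation baked into the dataset at build time (see
#' [buildPseudopopulation()] for why folds respect real-trial identity),
#' run independently for every resample. Features are standardized within
#' training folds only.
#'
#' @param dataset a [PseudoPopulationDataset-class].
#' @param cost SVM regularization parameter C (default 1).
#' @param group group label stored on the result.
#' @return A [DecodingResult-class] with one accuracy per resample.
#' @export
decodePopulation <- function(dataset, cost = 1, group = "all") {
  stopifnot(is(dataset, "PseudoPopulationDataset"))
  acc <- vapply(dataset@resamples, function(r) {
    if (length(unique(table(r$y))) > 1L)
      stop("internal error: unbalanced classes within a resample")
    cvAccuracy(r$x, r$y, r$fold, cost = cost)
  }, 0)
  new("DecodingResult", accuracies = acc,
      nullAccuracies = matrix(numeric(0), length(acc), 0), group = group)
}

#' Label-shuffle null distribution for a decoder
#'
#' Permutes class labels within each resample before cross-validation,
#' `nShuffles` times, giving an empirical chance distribution and an
#' empirical p-value for the observed mean accuracy
#' (`(1 + #null >= observed) / (1 + nShuffles)`).
#'
#' Labels are permuted within cross-validation folds (stratified
#' permutation). This preserves the dataset's class-balance invariant in
#' every training and test fold; permuting across folds leaves folds
#' imbalanced in complementary directions, which biases cross-validated
#' null accuracy below chance.
#'
#' @param dataset a [PseudoPopulationDataset-class].
#' @param nShuffles number of label permutations (>= 1).
#' @param cost as in [decodePopulation()].
#' @param observed optional [DecodingResult-class] to attach the null to
#'   and compute the empirical p against; computed if missing.
#' @param seed integer seed for the label permutations.
#' @return list: `result` (a [DecodingResult-class] carrying the null
#'   matrix), `nullMean`, `empiricalP`.
#' @export
shuffleControl <- function(dataset, nShuffles = 100L, cost = 1,
                           observed = NULL, seed = 1L) {
  if (nShuffles < 1) stop("nShuffles must be at least 1")
  if (is.null(observed))
    observed <- decodePopulation(dataset, cost = cost)
  nulls <- withSeed(childSeed(seed, 2), {
    vapply(seq_len(nShuffles), function(s) {
      vapply(dataset@resamples, function(r) {
        yPerm <- r$y
        for (f in unique(r$fold)) {
          idx <- which(r$fold == f)
          yPerm[idx] <- sample(r$y[idx])
        }
        cvAccuracy(r$x, yPerm, r$fold, cost = cost)
      }, 0)
    }, numeric(length(dataset@resamples)))
  })
  nulls <- matrix(nulls, nrow = length(dataset@resamples))
  obs <- mean(observed@accuracies)
  nullMeans <- colMeans(nulls)
  res <- new("DecodingResult", accuracies = observed@accuracies,
             nullAccuracies = nulls, group = observed@group)
  list(result = res, nullMean = mean(nulls),
       empiricalP = (1 + sum(nullMeans >= obs)) / (1 + nShuffles))
}

#' Compare decoding accuracy across groups
#'
#' Kruskal-Wallis omnibus test across the groups' per-resample accuracies
#' plus pairwise Wilcoxon rank-sum post-hoc comparisons with multiplicity
#' correction; with exactly two groups the omnibus reduces to the unpaired
#' rank-sum test.
#'
#' @param results named list of [DecodingResult-class] objects (or bare
#'   numeric accuracy vectors), one per group; at least two groups.
#' @param adjust p-adjustment method for the pairwise comparisons
#'   (default `"holm"`).
#' @return list: `omnibus` (`statistic`, `df`, `p`, `method`), `pairwise`
#'   (data.frame `groupA`, `groupB`, `statistic`, `p`, `pAdjusted`),
#'   `groupMeans`.
#' @export
compareDecoders <- function(results, adjust = "holm") {
  if (length(results) < 2L) stop("need at least two groups to compare")
  accs <- lapply(results, function(r)
    if (is(r, "DecodingResult")) r@accuracies else as.numeric(r))
  if (is.null(names(accs)) || any(names(accs) == ""))
    names(accs) <- paste0("group", seq_along(accs))
  x <- unlist(accs)
  g <- factor(rep(names(accs), lengths(accs)), levels = names(accs))
  if (length(accs) == 2L) {
    wt <- suppressWarnings(stats::wilcox.test(accs[[1]], accs[[2]]))
    omnibus <- list(statistic = unname(wt$statistic), df = NA_integer_,
                    p = wt$p.value, method = "Wilcoxon rank-sum")
  } else {
    kw <- stats::kruskal.test(x, g)
    omnibus <- list(statistic = unname(kw$statistic),
                    df = unname(kw$parameter), p = kw$p.value,
                    method = "Kruskal-Wallis")
  }
  cmb <- utils::combn(names(accs), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
    wt <- suppressWarnings(stats::wilcox.test(accs[[cmb[1, i]]],
                                              accs[[cmb[2, i]]]))
    data.frame(groupA = cmb[1, i], groupB = cmb[2, i],
               statistic = unname(wt$statistic), p = wt$p.value)
  }))
  pairwise$pAdjusted <- stats::p.adjust(pairwise$p, method = adjust)
  list(omnibus = omnibus, pairwise = pairwise,
       groupMeans = vapply(accs, mean, 0))
}
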