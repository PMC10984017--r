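# Internal helpers shared across modules.

#' Run code under a local RNG seed
#'
#' Saves the caller's RNG state, seeds, evaluates `code`, and restores the
#' state on exit, so generators are reproducible without leaking global
#' state between calls.
#'
#' @param seed integer scalar.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Standard error of the mean; NA for n < 2.
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Convert a logical per-frame mask into (startS, endS) intervals.
# Frame i (1-based) covers [ (i-1)/fps, i/fps ).  NA counts as FALSE.
maskToIntervals <- function(mask, fps) {
  mask <- !is.na(mask) & mask
  if (!any(mask)) {
    return(data.frame(startS = numeric(0), endS = numeric(0)))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(startS = (starts[keep] - 1L) / fps, endS = ends[keep] / fps)
}

# Merge intervals separated by gaps < mergeGapS, then drop intervals
# shorter than minDurS.  Input assumed sorted and non-overlapping.
postprocessIntervals <- function(iv, minDurS = 0, mergeGapS = 0) {
  if (nrow(iv) == 0L) return(iv)
  if (mergeGapS > 0 && nrow(iv) > 1L) {
    out <- iv[1L, , drop = FALSE]
    for (i in seq_len(nrow(iv))[-1L]) {
      if (iv$startS[i] - out$endS[nrow(out)] < mergeGapS) {
        out$endS[nrow(out)] <- iv$endS[i]
      } else {
        out <- rbind(out, iv[i, , drop = FALSE])
      }
    }
    iv <- out
  }
  iv <- iv[(iv$endS - iv$startS) >= minDurS, , drop = FALSE]
  rownames(iv) <- NULL
  iv
}

# Deterministic per-purpose child seeds derived from one master seed,
# kept inside 32-bit integer range.
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset) * 12347) %% 2147483629)
}
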