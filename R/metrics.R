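#' Temporal statistics of a state time course
#'
#' Binarizes the posterior probabilities by per-sample argmax (ties toward the
#' lower state index) — or by a probability threshold when `gammaThreshold`
#' is given — and computes, per state: fractional occupancy (FO, the fraction
#' of samples assigned), mean lifetime (LT, mean contiguous-visit duration)
#' and mean interval time (IT, mean gap between consecutive visits), the
#' latter two in milliseconds. Visits never span subject boundaries. A state
#' that is never (or only once) visited reports `NA` for the undefined
#' quantities rather than zero.
#'
#' @param x a [StateTimeCourse-class], or an integer state path.
#' @param fs sampling rate in Hz.
#' @param K number of states (required when `x` is a path).
#' @param lengths per-subject segment lengths (taken from the object when `x`
#'   is a [StateTimeCourse-class]).
#' @param gammaThreshold optional probability threshold: state k is "on" where
#'   `gamma[, k] > threshold` (occupancies then need not partition time);
#'   default `NULL` uses the argmax convention.
#' @return `data.frame` with columns `state`, `FO`, `LT_ms`, `IT_ms`, `nVisits`;
#'   per-visit durations are attached as `attr(, "visits")`.
#' @export
temporalStats <- function(x, fs, K = NULL, lengths = NULL, gammaThreshold = NULL) {
  if (is(x, "StateTimeCourse")) {
    if (is.null(lengths)) lengths <- x@subjectLengths
    K <- ncol(x@gamma)
    if (is.null(gammaThreshold)) {
      path <- max.col(x@gamma, ties.method = "first")
      active <- NULL
    } else {
      active <- x@gamma > gammaThreshold
      path <- NULL
    }
  } else {
    path <- as.integer(x)
    active <- NULL
    if (is.null(K)) K <- max(path)
    if (is.null(lengths)) lengths <- length(path)
  }
  T <- if (!is.null(path)) length(path) else nrow(active)
  stopifnot(sum(lengths) == T)

  visitLists <- rep(list(numeric(0)), K)
  gapLists <- rep(list(numeric(0)), K)
  onCounts <- numeric(K)
  off <- 0L
  for (len in lengths) {
    idx <- (off + 1L):(off + len)
    for (k in seq_len(K)) {
      on <- if (!is.null(path)) path[idx] == k else active[idx, k]
      onCounts[k] <- onCounts[k] + sum(on)
      r <- rle(on)
      ends <- cumsum(r$lengths)
      vis <- which(r$values)
      visitLists[[k]] <- c(visitLists[[k]], r$lengths[vis])
      if (length(vis) >= 2) {
        gaps <- ends[vis[-1] - 1L] - (ends[vis[-length(vis)]])
        gapLists[[k]] <- c(gapLists[[k]], gaps)
      }
    }
    off <- off + len
  }
  toMs <- 1000 / fs
  out <- data.frame(
    state = seq_len(K),
    FO = onCounts / T,
    LT_ms = vapply(visitLists, function(v) if (length(v)) mean(v) * toMs else NA_real_,
                   numeric(1)),
    IT_ms = vapply(gapLists, function(g) if (length(g)) mean(g) * toMs else NA_real_,
                   numeric(1)),
    nVisits = vapply(visitLists, length, integer(1)))
  attr(out, "visits") <- lapply(visitLists, function(v) v * toMs)
  attr(out, "intervals") <- lapply(gapLists, function(g) g * toMs)
  out
}

#' Epoch a state time course around stimulus onsets, with baseline correction
#'
#' Cuts the posterior state probabilities into per-trial windows of
#' `[-200, 1200]` ms around each onset and subtracts, per trial and state, the
#' mean over the pre-stimulus `[-200, -30]` ms baseline window. Onsets are
#' mapped through the embedding's dropped-edge index map so event alignment
#' survives the edge trimming; trials whose window falls outside the available
#' samples are dropped and counted.
#'
#' @param stc a [StateTimeCourse-class] (single subject) or a samples x K
#'   gamma matrix.
#' @param events an event table with column `onset_s` (and optionally
#'   `condition`).
#' @param fs sampling rate in Hz.
#' @param indexMap original-sample indices of the gamma rows (from
#'   [buildEmbedded()]); default assumes no trimming.
#' @param window epoch window in seconds (default `c(-0.2, 1.2)`).
#' @param baseline baseline window in seconds (default `c(-0.2, -0.03)`);
#'   edges are rounded to the nearest sample.
#' @return An [EpochedCourse-class].
#' @export
epochStates <- function(stc, events, fs, indexMap = NULL,
                        window = c(-0.2, 1.2), baseline = c(-0.2, -0.03)) {
  gamma <- if (is(stc, "StateTimeCourse")) stc@gamma else as.matrix(stc)
  K <- ncol(gamma)
  if (is.null(indexMap)) indexMap <- seq_len(nrow(gamma))
  rel <- round(window[1] * fs):round(window[2] * fs)
  times <- rel / fs
  basel <- which(rel >= round(baseline[1] * fs) & rel <= round(baseline[2] * fs))
  if (length(basel) == 0) stop("baseline window contains no samples")
  # position of each original sample in the trimmed gamma timeline
  first <- indexMap[1]
  onsetSample <- round(events$onset_s * fs) + 1L
  pos <- onsetSample - first + 1L

  keep <- pos + rel[1] >= 1L & pos + rel[length(rel)] <= nrow(gamma)
  nDropped <- sum(!keep)
  trials <- which(keep)
  out <- array(NA_real_, c(length(trials), length(rel), K))
  for (i in seq_along(trials)) {
    seg <- gamma[pos[trials[i]] + rel, , drop = FALSE]
    bl <- colMeans(seg[basel, , drop = FALSE])
    out[i, , ] <- sweep(seg, 2, bl)
  }
  cond <- if (!is.null(events$condition)) factor(events$condition[trials])
          else factor(rep("all", length(trials)))
  new("EpochedCourse", data = out, times = times, conditions = cond,
      nDropped = as.integer(nDropped))
}
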