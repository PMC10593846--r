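#' Symmetric leakage orthogonalization
#'
#' Removes zero-lag (instantaneous) signal leakage between regions by
#' replacing the demeaned data matrix with its closest matrix (Frobenius norm)
#' having mutually orthogonal rows — the orthonormal polar factor of the SVD —
#' rescaled so every region keeps its original RMS amplitude. The construction
#' is symmetric: no region is a reference, and permuting regions before or
#' after gives the same result. All pairwise zero-lag correlations of the
#' output are exactly zero.
#'
#' @param rec a [Recording-class]; rows must be linearly independent.
#' @return A [Recording-class] with orthogonal, zero-mean rows at the original
#'   row norms.
#' @export
orthogonalizeSymmetric <- function(rec) {
  stopifnot(is(rec, "Recording"))
  X <- rec@data
  X <- X - rowMeans(X)
  s <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * s$d[1]
  if (any(s$d <= tol)) {
    bad <- which(s$d <= tol)
    stop(sprintf(
      "rank-deficient recording: rank %d < %d regions (singular value(s) %s vanish); cannot orthogonalize",
      min(bad) - 1L, nrow(X), paste(bad, collapse = ",")))
  }
  O <- s$u %*% t(s$v)                     # closest orthonormal-row matrix
  scale <- sqrt(rowSums(X^2))             # restore per-region norms
  Recording(O * scale, rec@fs, rec@regionNames, rec@subjectId)
}

#' Time-delay embedding specification
#'
#' @param lags ordered integer lags; default `-7:7` (15 lagged copies, a 60 ms
#'   window at 250 Hz).
#' @param nComponents number of principal components to retain; default
#'   `2 * nRegions` supplied at fit time.
#' @return List of class `EmbeddingSpec`.
#' @export
embeddingSpec <- function(lags = -7:7, nComponents = NULL) {
  lags <- as.integer(sort(lags))
  structure(list(lags = lags, nComponents = nComponents),
            class = c("EmbeddingSpec", "list"))
}

#' Build the time-delay embedded matrix
#'
#' Stacks lagged copies of every region's time series: row (r, l) at output
#' time t equals region r at original time t + l. The `max(|lags|)` samples at
#' each edge, where some lag is unavailable, are dropped; `indexMap` records
#' the surviving original sample indices so downstream event alignment stays
#' exact.
#'
#' @param rec a [Recording-class].
#' @param lags integer lags (default `-7:7`).
#' @return List of class `TimeDelayEmbedding`: `matrix`
#'   ((regions x lags) x valid samples, rows grouped by region), `indexMap`,
#'   `lags`, `nRegions`, `fs`.
#' @export
buildEmbedded <- function(rec, lags = -7:7) {
  stopifnot(is(rec, "Recording"))
  lags <- as.integer(sort(lags))
  X <- rec@data
  T <- ncol(X); R <- nrow(X)
  lo <- -min(lags); hi <- max(lags)       # samples trimmed at start / end
  valid <- (1L + max(lo, 0L)):(T - max(hi, 0L))
  if (T <= 2L * max(abs(lags)) || length(valid) < 1L)
    stop(sprintf("recording too short: %d samples for lags spanning [%d, %d]",
                 T, min(lags), max(lags)))
  L <- length(lags)
  E <- matrix(0, R * L, length(valid))
  rn <- character(R * L)
  for (r in seq_len(R)) {
    for (li in seq_len(L)) {
      row <- (r - 1L) * L + li
      E[row, ] <- X[r, valid + lags[li]]
      rn[row] <- sprintf("%s_lag%+d", rec@regionNames[r], lags[li])
    }
  }
  rownames(E) <- rn
  structure(list(matrix = E, indexMap = valid, lags = lags,
                 nRegions = R, fs = rec@fs),
            class = c("TimeDelayEmbedding", "list"))
}

#' Extract the lag-0 rows of an embedding
#'
#' @param emb a `TimeDelayEmbedding`.
#' @return regions x valid-samples matrix equal to the original interior
#'   samples.
#' @export
lagZero <- function(emb) {
  li <- which(emb$lags == 0L)
  stopifnot(length(li) == 1L)
  idx <- (seq_len(emb$nRegions) - 1L) * length(emb$lags) + li
  emb$matrix[idx, , drop = FALSE]
}

#' Fit PCA on an embedded matrix and project
#'
#' Centers the embedded features, computes the eigendecomposition of their
#' covariance, and retains the leading `nComponents` components. For group
#' analyses pass the column-wise concatenation across subjects so the basis is
#' shared.
#'
#' @param E features x samples matrix (an embedding's `matrix`, possibly
#'   concatenated across subjects).
#' @param nComponents components to keep, P.
#' @return List of class `PCAModel`: `mean` (feature means), `loadings`
#'   (features x P, orthonormal columns), `explained` (non-increasing variance
#'   fractions, all ranks), `scores` (P x samples).
#' @export
pcaReduce <- function(E, nComponents) {
  nComponents <- as.integer(nComponents)
  if (nComponents < 1L) stop("nComponents must be >= 1")
  if (nComponents > nrow(E))
    stop(sprintf("nComponents (%d) exceeds the %d embedded features",
                 nComponents, nrow(E)))
  mu <- rowMeans(E)
  Ec <- E - mu
  C <- tcrossprod(Ec) / (ncol(E) - 1L)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  rank <- sum(vals > max(vals) * 1e-12)
  if (nComponents > rank)
    stop(sprintf("nComponents (%d) exceeds the available rank (%d)",
                 nComponents, rank))
  W <- e$vectors[, seq_len(nComponents), drop = FALSE]
  structure(list(mean = mu, loadings = W, explained = vals / sum(vals),
                 scores = crossprod(W, Ec)),
            class = c("PCAModel", "list"))
}

#' Z-score each region of a recording
#'
#' Per-subject standardization applied before group-level embedding so no
#' subject or region dominates the shared PCA basis.
#'
#' @param rec a [Recording-class].
#' @return A standardized [Recording-class].
#' @export
standardizeRecording <- function(rec) {
  X <- rec@data
  X <- (X - rowMeans(X)) / apply(X, 1, stats::sd)
  Recording(X, rec@fs, rec@regionNames, rec@subjectId)
}

#' Preprocess a list of recordings for HMM fitting
#'
#' Runs the full preparation chain: per-subject standardization, symmetric
#' leakage orthogonalization, time-delay embedding, then a single group PCA on
#' the concatenation across subjects.
#'
#' @param recs list of [Recording-class] objects with equal region counts.
#' @param lags integer lags (default `-7:7`).
#' @param nComponents principal components P; default `2 * nRegions`.
#' @param standardize z-score each region per subject first (default TRUE).
#' @param orthogonalize apply symmetric leakage correction (default TRUE).
#' @param standardizeScores z-score the PCA scores before returning them
#'   (default FALSE: the HMM states are defined by covariance structure, which
#'   whitening would distort).
#' @return List: `scores` (samples x P, concatenated), `lengths` (per-subject
#'   valid-sample counts), `indexMaps` (per-subject original-sample indices),
#'   `pca` (the `PCAModel`), `lags`, `fs`.
#' @export
prepareData <- function(recs, lags = -7:7, nComponents = NULL,
                        standardize = TRUE, orthogonalize = TRUE,
                        standardizeScores = FALSE) {
  if (is(recs, "Recording")) recs <- list(recs)
  nr <- vapply(recs, function(r) nrow(r@data), integer(1))
  if (length(unique(nr)) != 1L)
    stop(sprintf("inconsistent region counts across subjects: %s",
                 paste(nr, collapse = ", ")))
  if (is.null(nComponents)) nComponents <- 2L * nr[1]
  embs <- lapply(recs, function(r) {
    if (standardize) r <- standardizeRecording(r)
    if (orthogonalize) r <- orthogonalizeSymmetric(r)
    buildEmbedded(r, lags)
  })
  E <- do.call(cbind, lapply(embs, `[[`, "matrix"))
  pca <- pcaReduce(E, nComponents)
  if (standardizeScores)
    pca$scores <- pca$scores / apply(pca$scores, 1, stats::sd)
  list(scores = t(pca$scores),
       lengths = vapply(embs, function(e) length(e$indexMap), integer(1)),
       indexMaps = lapply(embs, `[[`, "indexMap"),
       pca = pca, lags = embs[[1]]$lags, fs = recs[[1]]@fs)
}
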