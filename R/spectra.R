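#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-half-bandwidth
#' `nw`, as eigenvectors of the standard symmetric tridiagonal matrix. Tapers
#' are orthonormal; signs follow the usual convention (non-negative mean for
#' even-order tapers, positive initial slope otherwise).
#'
#' @param n taper length in samples.
#' @param nw time-half-bandwidth product (default 4).
#' @param k number of tapers (default `2 * nw - 1`).
#' @return n x k matrix of tapers.
#' @export
dpssTapers <- function(n, nw = 4, k = 2 * nw - 1) {
  stopifnot(n > k, nw > 0)
  W <- nw / n
  t0 <- 0:(n - 1)
  M <- matrix(0, n, n)
  diag(M) <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * W)
  off <- t0[-1] * (n - t0[-1]) / 2
  M[cbind(1:(n - 1), 2:n)] <- off
  M[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(M, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sum(V[, j])
    if (abs(s) > 1e-10) {
      if (s < 0) V[, j] <- -V[, j]
    } else if (V[2, j] - V[1, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' State-weighted multitaper spectra and coherence
#'
#' Estimates per-state power spectral density and coherence by weighting
#' windowed multitaper cross-spectra with the window's mean posterior state
#' probability: the recording is cut into overlapping windows; each window's
#' DPSS multitaper cross-spectrum contributes to state k with weight equal to
#' the window-mean of `gamma[, k]`; the state cross-spectrum is the weighted
#' average across windows. PSD is the (real) diagonal; coherence is
#' `|S_ij| / sqrt(S_ii S_jj)`.
#'
#' @param rec a [Recording-class].
#' @param stc a [StateTimeCourse-class] or gamma matrix aligned to the
#'   recording through `indexMap`.
#' @param indexMap original-sample indices of the gamma rows (from the
#'   embedding); `NULL` when gamma covers every sample.
#' @param band frequency band in Hz to retain (default `c(1, 40)`).
#' @param windowS window length in seconds (default 2).
#' @param overlap fractional window overlap (default 0.5).
#' @param nw time-half-bandwidth (default 4).
#' @param nTapers number of DPSS tapers (default 7).
#' @return A [SpectralEstimate-class]. States whose total posterior weight is
#'   ~0 get `NA` spectra and a warning naming the state.
#' @export
weightedMultitaper <- function(rec, stc, indexMap = NULL, band = c(1, 40),
                               windowS = 2, overlap = 0.5, nw = 4, nTapers = 7) {
  stopifnot(is(rec, "Recording"))
  gamma <- if (is(stc, "StateTimeCourse")) stc@gamma else as.matrix(stc)
  X <- rec@data
  if (!is.null(indexMap)) X <- X[, indexMap, drop = FALSE]
  if (ncol(X) != nrow(gamma))
    stop(sprintf("gamma (%d samples) is not aligned to the recording (%d samples)",
                 nrow(gamma), ncol(X)))
  fs <- rec@fs
  R <- nrow(X); K <- ncol(gamma)
  win <- round(windowS * fs)
  if (win > ncol(X)) stop("recording shorter than one spectral window")
  step <- max(1L, round(win * (1 - overlap)))
  starts <- seq(1L, ncol(X) - win + 1L, by = step)
  tapers <- dpssTapers(win, nw, nTapers)
  freqsAll <- (0:(win %/% 2)) * fs / win
  sel <- which(freqsAll >= band[1] & freqsAll <= band[2])
  freqs <- freqsAll[sel]
  nf <- length(sel)

  num <- lapply(seq_len(K), function(k) array(0 + 0i, c(nf, R, R)))
  den <- numeric(K)
  for (st in starts) {
    idx <- st:(st + win - 1L)
    xw <- t(X[, idx, drop = FALSE])
    xw <- sweep(xw, 2, colMeans(xw))
    Farr <- array(0 + 0i, c(nf, R, nTapers))
    for (tp in seq_len(nTapers))
      Farr[, , tp] <- stats::mvfft(xw * tapers[, tp])[sel, , drop = FALSE]
    Sw <- array(0 + 0i, c(nf, R, R))
    for (f in seq_len(nf)) {
      Mf <- matrix(Farr[f, , ], R, nTapers)
      Sw[f, , ] <- tcrossprod(Mf, Conj(Mf)) / nTapers
    }
    w <- colMeans(gamma[idx, , drop = FALSE])
    for (k in seq_len(K)) {
      if (w[k] > 0) num[[k]] <- num[[k]] + w[k] * Sw
      den[k] <- den[k] + w[k]
    }
  }

  psd <- array(NA_real_, c(K, nf, R))
  coh <- array(NA_real_, c(K, nf, R, R))
  scale <- 2 / fs
  for (k in seq_len(K)) {
    if (den[k] < length(starts) * 1e-8) {
      warning(sprintf("state %d carried ~0 posterior weight; spectra reported missing", k))
      next
    }
    S <- num[[k]] / den[k]
    for (f in seq_len(nf)) {
      Sf <- S[f, , ]
      p <- pmax(Re(diag(Sf)), 0)
      psd[k, f, ] <- p * scale
      dn <- sqrt(outer(p, p))
      cf <- Mod(Sf) / dn
      cf[dn == 0] <- 0
      diag(cf) <- 1
      coh[k, f, , ] <- pmin(pmax(cf, 0), 1)
    }
  }
  new("SpectralEstimate", freqs = freqs, psd = psd, coh = coh,
      subjectId = rec@subjectId,
      params = list(windowS = windowS, overlap = overlap, nw = nw,
                    nTapers = nTapers, band = band, nWindows = length(starts),
                    stateWeights = den))
}

# assemble the non-negative (frequency x features) matrix from estimates
spectraToMatrix <- function(estimates, what = "both") {
  if (is(estimates, "SpectralEstimate")) estimates <- list(estimates)
  freqs <- estimates[[1]]@freqs
  cols <- list(); info <- list()
  for (s in seq_along(estimates)) {
    est <- estimates[[s]]
    if (max(abs(est@freqs - freqs)) > 1e-9)
      stop("all spectral estimates must share the frequency grid")
    K <- dim(est@psd)[1]; R <- dim(est@psd)[3]
    for (k in seq_len(K)) {
      if (anyNA(est@psd[k, , ])) next
      if (what %in% c("both", "psd")) {
        for (r in seq_len(R)) {
          cols[[length(cols) + 1L]] <- est@psd[k, , r]
          info[[length(info) + 1L]] <- data.frame(subject = s, state = k,
                                                  kind = "psd", i = r, j = r)
        }
      }
      if (what %in% c("both", "coherence")) {
        for (i in seq_len(R - 1)) for (j in (i + 1):R) {
          cols[[length(cols) + 1L]] <- est@coh[k, , i, j]
          info[[length(info) + 1L]] <- data.frame(subject = s, state = k,
                                                  kind = "coh", i = i, j = j)
        }
      }
    }
  }
  list(V = do.call(cbind, cols), info = do.call(rbind, info), freqs = freqs)
}

# multiplicative-update NNMF (Frobenius objective)
nnmfUpdate <- function(V, M, maxIter, tol) {
  eps <- 1e-12
  nf <- nrow(V); nc <- ncol(V)
  W <- matrix(runif(nf * M, 0.1, 1), nf, M) * sqrt(mean(V) / M)
  H <- matrix(runif(M * nc, 0.1, 1), M, nc) * sqrt(mean(V) / M)
  nv <- sqrt(sum(V^2))
  res <- Inf
  trace <- numeric(0)
  for (it in seq_len(maxIter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    newRes <- sqrt(sum((V - W %*% H)^2)) / nv
    trace <- c(trace, newRes)
    if (is.finite(res) && res - newRes < tol) { res <- newRes; break }
    res <- newRes
  }
  list(W = W, H = H, residual = res, trace = trace)
}

#' Non-negative frequency modes of the spectral content
#'
#' Factorizes the stacked spectra — every (subject, state, region) PSD and
#' every (subject, state, connection) coherence spectrum — into `M`
#' non-negative frequency profiles with non-negative loadings, by
#' multiplicative-update NNMF (Frobenius objective, best of `nRestarts`
#' seeded restarts). Modes are ordered by peak frequency, ascending, and
#' profile columns are scaled to unit maximum. With the default `M = 4` the
#' highest (low-gamma) mode is computed like the others but flagged
#' `disregarded` in the returned feature info, reflecting the PCA-induced
#' high-frequency bias of the embedding pipeline.
#'
#' @param estimates a [SpectralEstimate-class] or list of them (one per
#'   subject) on a shared frequency grid.
#' @param M number of modes (default 4).
#' @param what factorize `"both"` PSD and coherence jointly (default), or
#'   `"psd"` / `"coherence"` separately.
#' @param nRestarts random restarts (default 3).
#' @param maxIter maximum multiplicative updates (default 500).
#' @param tol stop when the relative residual improves by less (default 1e-8).
#' @param seed integer seed.
#' @return A [SpectralModes-class]; the residual trace of the winning restart
#'   is attached as `attr(, "trace")`.
#' @export
nnmfModes <- function(estimates, M = 4, what = c("both", "psd", "coherence"),
                      nRestarts = 3, maxIter = 500, tol = 1e-8, seed = 1) {
  what <- match.arg(what)
  sm <- spectraToMatrix(estimates, what)
  if (any(sm$V < 0)) stop("spectral matrix has negative entries; PSD and coherence must be non-negative")
  set.seed(seed)
  runs <- lapply(seq_len(nRestarts), function(r) nnmfUpdate(sm$V, M, maxIter, tol))
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "residual"))]]
  ord <- order(sm$freqs[apply(best$W, 2, which.max)])
  W <- best$W[, ord, drop = FALSE]
  H <- best$H[ord, , drop = FALSE]
  sc <- apply(W, 2, max)
  W <- sweep(W, 2, sc, "/")
  H <- sweep(H, 1, sc, "*")
  info <- sm$info
  modesPeak <- sm$freqs[apply(W, 2, which.max)]
  out <- new("SpectralModes", W = W, H = H, freqs = sm$freqs,
             featureInfo = info, residual = best$residual)
  attr(out, "trace") <- best$trace
  attr(out, "disregarded") <- if (M >= 4) which.max(modesPeak) else integer(0)
  out
}

#' Project spectra onto frequency modes; z-scored power maps
#'
#' The mode-projected quantity is the inner product over frequency of each
#' spectrum with the mode profile. Group results average across subjects;
#' power maps are z-scored across regions per (state, mode).
#'
#' @param estimates a [SpectralEstimate-class] or list of them.
#' @param modes a [SpectralModes-class] on the same frequency grid.
#' @return List: `psdMaps` (states x modes x regions, z-scored group means),
#'   `psdRaw` (same, unstandardized), `cohNets` (states x modes x regions x
#'   regions group-mean projected coherence, zero diagonal).
#' @export
projectModes <- function(estimates, modes) {
  if (is(estimates, "SpectralEstimate")) estimates <- list(estimates)
  stopifnot(is(modes, "SpectralModes"))
  if (max(abs(estimates[[1]]@freqs - modes@freqs)) > 1e-9)
    stop("frequency grids of estimates and modes differ")
  K <- dim(estimates[[1]]@psd)[1]
  R <- dim(estimates[[1]]@psd)[3]
  M <- ncol(modes@W)
  nS <- length(estimates)
  psdS <- array(NA_real_, c(nS, K, M, R))
  cohS <- array(NA_real_, c(nS, K, M, R, R))
  for (s in seq_len(nS)) {
    est <- estimates[[s]]
    for (k in seq_len(K)) {
      if (anyNA(est@psd[k, , ])) next
      psdS[s, k, , ] <- crossprod(modes@W, est@psd[k, , ])           # M x R
      for (m in seq_len(M)) {
        Sm <- apply(est@coh[k, , , ] * modes@W[, m], c(2, 3), sum)
        diag(Sm) <- 0
        cohS[s, k, m, , ] <- Sm
      }
    }
  }
  psdRaw <- apply(psdS, c(2, 3, 4), mean, na.rm = TRUE)
  cohNets <- apply(cohS, c(2, 3, 4, 5), mean, na.rm = TRUE)
  psdMaps <- psdRaw
  for (k in seq_len(K)) for (m in seq_len(M))
    psdMaps[k, m, ] <- zscore0(psdRaw[k, m, ])
  list(psdMaps = psdMaps, psdRaw = psdRaw, cohNets = cohNets)
}

#' Gaussian-mixture thresholding of connection values
#'
#' Fits a two-component univariate Gaussian mixture to pooled connection
#' values and keeps the connections whose posterior probability under the
#' higher-mean component exceeds 0.5 — separating the "strong" connections
#' from the bulk. Degenerate fits (zero-variance component, or too few
#' distinct values) fall back to a percentile threshold with a warning.
#'
#' @param values numeric vector of connection strengths.
#' @param fallbackQuantile percentile used when the mixture fit degenerates
#'   (default 0.9).
#' @param arctanh apply a Fisher transform before fitting (default FALSE; raw
#'   coherence projections are fitted).
#' @return List: `keep` (logical), `means`, `sds`, `weights`, `threshold`
#'   (smallest kept value; `Inf` when nothing is kept), `fallback` flag.
#' @export
gmmThreshold <- function(values, fallbackQuantile = 0.9, arctanh = FALSE) {
  x <- as.numeric(values)
  if (length(x) < 4) stop("need at least twice as many connections as mixture components")
  xf <- if (arctanh) atanh(pmin(pmax(x, 0), 1 - 1e-12)) else x
  fit <- NULL
  mclustBIC <- mclust::mclustBIC   # Mclust() resolves this in the caller frame
  if (length(unique(xf)) >= 3)
    fit <- tryCatch(
      suppressWarnings(mclust::Mclust(xf, G = 2, modelNames = "V", verbose = FALSE)),
      error = function(e) NULL)
  degenerate <- is.null(fit) || any(sqrt(fit$parameters$variance$sigmasq) < 1e-10)
  if (degenerate) {
    warning("degenerate Gaussian mixture; falling back to percentile threshold")
    thr <- stats::quantile(xf, fallbackQuantile, names = FALSE)
    keep <- xf > thr
    return(list(keep = keep, means = NA_real_, sds = NA_real_,
                weights = NA_real_,
                threshold = if (any(keep)) min(x[keep]) else Inf,
                fallback = TRUE))
  }
  hi <- which.max(fit$parameters$mean)
  keep <- fit$z[, hi] > 0.5
  list(keep = keep,
       means = as.numeric(fit$parameters$mean),
       sds = sqrt(as.numeric(fit$parameters$variance$sigmasq)),
       weights = as.numeric(fit$parameters$pro),
       threshold = if (any(keep)) min(x[keep]) else Inf,
       fallback = FALSE)
}

#' Threshold the projected coherence networks of every (state, mode)
#'
#' Applies [gmmThreshold()] to the upper-triangle connection values of each
#' (state, mode) projected coherence matrix and returns the surviving edges.
#'
#' @param proj result of [projectModes()].
#' @param ... passed to [gmmThreshold()].
#' @return List: `edges` (data.frame `state, mode, region_i, region_j, value`)
#'   and `fits` (per state-mode mixture summaries).
#' @export
thresholdNetworks <- function(proj, ...) {
  K <- dim(proj$cohNets)[1]; M <- dim(proj$cohNets)[2]; R <- dim(proj$cohNets)[3]
  ut <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  edges <- list(); fits <- list()
  for (k in seq_len(K)) for (m in seq_len(M)) {
    vals <- proj$cohNets[k, m, , ][ut]
    if (anyNA(vals)) next
    g <- gmmThreshold(vals, ...)
    fits[[sprintf("state%d_mode%d", k, m)]] <- g
    if (any(g$keep))
      edges[[length(edges) + 1L]] <- data.frame(
        state = k, mode = m, region_i = ut[g$keep, 1], region_j = ut[g$keep, 2],
        value = vals[g$keep])
  }
  list(edges = if (length(edges)) do.call(rbind, edges) else
         data.frame(state = integer(), mode = integer(), region_i = integer(),
                    region_j = integer(), value = numeric()),
       fits = fits)
}
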