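#' @import methods
#' @importFrom stats quantile rnorm runif sd cor cov var median setNames
#' @importFrom utils head read.delim write.table packageVersion
#' @useDynLib tdehmm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Multichannel recording
#'
#' Container for a parcellated source-space recording: a regions x samples
#' real matrix with its sampling rate and region labels. This is the raw
#' input of the pipeline.
#'
#' @slot data numeric matrix, regions x samples.
#' @slot fs sampling rate in Hz.
#' @slot regionNames character vector, one label per region (row).
#' @slot subjectId subject label.
#' @export
setClass("Recording",
  representation(data = "matrix", fs = "numeric",
                 regionNames = "character", subjectId = "character"))

setValidity("Recording", function(object) {
  d <- object@data
  if (!is.numeric(d)) return("data must be a numeric matrix")
  if (any(!is.finite(d))) return("data contains non-finite values")
  if (length(object@fs) != 1L || object@fs <= 0) return("fs must be a single positive number")
  if (length(object@regionNames) != nrow(d))
    return(sprintf("regionNames length (%d) != number of regions (%d)",
                   length(object@regionNames), nrow(d)))
  TRUE
})

#' Construct a Recording
#'
#' @param data regions x samples numeric matrix.
#' @param fs sampling rate, Hz.
#' @param regionNames optional region labels; defaults to `R01, R02, ...`.
#' @param subjectId subject label.
#' @return A [Recording-class] object.
#' @export
Recording <- function(data, fs, regionNames = NULL, subjectId = "S01") {
  data <- as.matrix(data)
  if (is.null(regionNames))
    regionNames <- sprintf("R%02d", seq_len(nrow(data)))
  new("Recording", data = data, fs = as.numeric(fs),
      regionNames = as.character(regionNames), subjectId = subjectId)
}

#' State time course (posterior state probabilities)
#'
#' Per-sample posterior probability of each hidden state given the data and
#' the model (the HMM "gamma"), computed by the forward-backward algorithm.
#' Rows sum to one.
#'
#' @slot gamma samples x K matrix of posterior probabilities.
#' @slot xi K x K matrix of summed pairwise transition posteriors.
#' @slot subjectLengths integer vector of per-subject segment lengths
#'   (the gamma rows are their concatenation).
#' @slot logLik log normalizer accumulated by the forward pass.
#' @export
setClass("StateTimeCourse",
  representation(gamma = "matrix", xi = "matrix",
                 subjectLengths = "integer", logLik = "numeric"))

setValidity("StateTimeCourse", function(object) {
  g <- object@gamma
  if (any(g < -1e-12) || any(g > 1 + 1e-12)) return("gamma entries must lie in [0,1]")
  if (any(abs(rowSums(g) - 1) > 1e-8)) return("gamma rows must sum to 1 within 1e-8")
  if (sum(object@subjectLengths) != nrow(g))
    return("subjectLengths must sum to nrow(gamma)")
  TRUE
})

StateTimeCourse <- function(gamma, xi = matrix(0, ncol(gamma), ncol(gamma)),
                            subjectLengths = nrow(gamma), logLik = NA_real_) {
  new("StateTimeCourse", gamma = gamma, xi = xi,
      subjectLengths = as.integer(subjectLengths), logLik = logLik)
}

#' Gaussian-observation hidden Markov model parameters
#'
#' Point parameters (posterior means under the variational fit) of a K-state
#' HMM with zero-mean (by default) Gaussian emissions in P dimensions: initial
#' distribution, row-stochastic transition matrix and one covariance per state.
#'
#' @slot K number of states.
#' @slot P observation dimension.
#' @slot pi initial state distribution.
#' @slot A K x K row-stochastic transition matrix.
#' @slot mu K x P matrix of state means (all-zero unless means were freed).
#' @slot Sigma list of K symmetric positive-definite P x P covariances.
#' @slot priors list of prior hyperparameters used by the fit.
#' @slot freeEnergy free-energy trace across iterations of the best restart.
#' @slot seed integer seed the fit was run with.
#' @export
setClass("HMMModel",
  representation(K = "integer", P = "integer", pi = "numeric", A = "matrix",
                 mu = "matrix", Sigma = "list", priors = "list",
                 freeEnergy = "numeric", seed = "integer"))

setValidity("HMMModel", function(object) {
  K <- object@K; P <- object@P
  if (length(object@pi) != K) return("pi must have length K")
  if (abs(sum(object@pi) - 1) > 1e-8) return("pi must sum to 1")
  if (!all(dim(object@A) == c(K, K))) return("A must be K x K")
  if (any(abs(rowSums(object@A) - 1) > 1e-10)) return("rows of A must sum to 1 within 1e-10")
  if (length(object@Sigma) != K) return("Sigma must hold K matrices")
  for (k in seq_len(K)) {
    S <- object@Sigma[[k]]
    if (!all(dim(S) == c(P, P))) return(sprintf("Sigma[[%d]] must be P x P", k))
    if (max(abs(S - t(S))) > 1e-8) return(sprintf("Sigma[[%d]] must be symmetric", k))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return(sprintf("Sigma[[%d]] must be positive-definite", k))
  }
  TRUE
})

#' Construct an HMMModel from point parameters
#'
#' @param pi initial distribution (length K).
#' @param A K x K row-stochastic transition matrix.
#' @param Sigma list of K P x P covariance matrices.
#' @param mu optional K x P mean matrix (default zero).
#' @param priors,freeEnergy,seed metadata slots.
#' @return An [HMMModel-class].
#' @export
HMMModel <- function(pi, A, Sigma, mu = NULL, priors = list(),
                     freeEnergy = numeric(), seed = NA_integer_) {
  K <- length(pi); P <- nrow(Sigma[[1]])
  if (is.null(mu)) mu <- matrix(0, K, P)
  new("HMMModel", K = as.integer(K), P = as.integer(P), pi = pi, A = A,
      mu = mu, Sigma = Sigma, priors = priors,
      freeEnergy = as.numeric(freeEnergy), seed = as.integer(seed))
}

#' Event-locked, baseline-corrected state occupancy
#'
#' Epochs of the state time course around stimulus onsets, baseline-corrected
#' against the pre-stimulus window.
#'
#' @slot data trials x timepoints x K array.
#' @slot times time axis in seconds relative to stimulus onset.
#' @slot conditions factor of per-trial condition labels.
#' @slot nDropped number of trials dropped for incomplete windows.
#' @export
setClass("EpochedCourse",
  representation(data = "array", times = "numeric",
                 conditions = "factor", nDropped = "integer"))

setValidity("EpochedCourse", function(object) {
  d <- dim(object@data)
  if (length(d) != 3) return("data must be trials x timepoints x K")
  if (length(object@times) != d[2]) return("times length must match timepoints")
  if (length(object@conditions) != d[1]) return("one condition label per trial")
  TRUE
})

#' Per-subject state-resolved spectral estimate
#'
#' Gamma-weighted multitaper power spectral density and coherence for each
#' state of one subject on a common frequency grid.
#'
#' @slot freqs frequency grid, Hz.
#' @slot psd K x nfreq x regions array (non-negative; NA when a state carried
#'   no posterior weight).
#' @slot coh K x nfreq x regions x regions coherence array, entries in [0,1],
#'   symmetric with unit diagonal.
#' @slot subjectId subject label.
#' @slot params multitaper parameters used.
#' @export
setClass("SpectralEstimate",
  representation(freqs = "numeric", psd = "array", coh = "array",
                 subjectId = "character", params = "list"))

setValidity("SpectralEstimate", function(object) {
  p <- object@psd; co <- object@coh
  if (length(dim(p)) != 3) return("psd must be K x nfreq x regions")
  if (length(dim(co)) != 4) return("coh must be K x nfreq x regions x regions")
  if (dim(p)[2] != length(object@freqs)) return("psd frequency axis mismatch")
  if (any(p < -1e-12, na.rm = TRUE)) return("psd must be non-negative")
  if (any(co < -1e-9 | co > 1 + 1e-9, na.rm = TRUE)) return("coherence must lie in [0,1]")
  TRUE
})

#' Non-negative frequency modes of a spectral collection
#'
#' NNMF factorization of all (subject, state) power spectra and coherence
#' spectra into a small number of non-negative frequency profiles with
#' non-negative loadings.
#'
#' @slot W nfreq x M matrix of mode profiles (columns ordered by peak
#'   frequency, ascending; scaled to unit maximum).
#' @slot H M x features matrix of loadings.
#' @slot freqs frequency grid, Hz.
#' @slot featureInfo data.frame describing each loading column
#'   (subject, state, kind, region / pair).
#' @slot residual final relative Frobenius residual.
#' @export
setClass("SpectralModes",
  representation(W = "matrix", H = "matrix", freqs = "numeric",
                 featureInfo = "data.frame", residual = "numeric"))

setValidity("SpectralModes", function(object) {
  if (any(object@W < 0) || any(object@H < 0)) return("W and H must be non-negative")
  if (nrow(object@W) != length(object@freqs)) return("W rows must match frequency grid")
  if (ncol(object@W) != nrow(object@H)) return("W and H inner dimensions must agree")
  TRUE
})
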