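#' Accessors
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param x an object.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("recData", function(x) standardGeneric("recData"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("stateProbs", function(x) standardGeneric("stateProbs"))
#' @rdname accessors
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))
#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))
#' @rdname accessors
#' @export
setGeneric("stateCovariances", function(x) standardGeneric("stateCovariances"))
#' @rdname accessors
#' @export
setGeneric("freeEnergy", function(x) standardGeneric("freeEnergy"))
#' @rdname accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @rdname accessors
#' @export
setMethod("recData", "Recording", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("samplingRate", "Recording", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("regionNames", "Recording", function(x) x@regionNames)
#' @rdname accessors
#' @export
setMethod("subjectId", "Recording", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("stateProbs", "StateTimeCourse", function(x) x@gamma)
#' @rdname accessors
#' @export
setMethod("nStates", "StateTimeCourse", function(x) ncol(x@gamma))
#' @rdname accessors
#' @export
setMethod("nStates", "HMMModel", function(x) x@K)
#' @rdname accessors
#' @export
setMethod("transitionMatrix", "HMMModel", function(x) x@A)
#' @rdname accessors
#' @export
setMethod("stateCovariances", "HMMModel", function(x) x@Sigma)
#' @rdname accessors
#' @export
setMethod("freeEnergy", "HMMModel", function(x) x@freeEnergy)
#' @rdname accessors
#' @export
setMethod("frequencies", "SpectralEstimate", function(x) x@freqs)
#' @rdname accessors
#' @export
setMethod("frequencies", "SpectralModes", function(x) x@freqs)

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording '%s': %d regions x %d samples at %g Hz (%.1f s)\n",
              object@subjectId, nrow(object@data), ncol(object@data),
              object@fs, ncol(object@data) / object@fs))
})

setMethod("show", "StateTimeCourse", function(object) {
  cat(sprintf("StateTimeCourse: %d samples x %d states, %d subject(s), logLik %.2f\n",
              nrow(object@gamma), ncol(object@gamma),
              length(object@subjectLengths), object@logLik))
})

setMethod("show", "HMMModel", function(object) {
  cat(sprintf("HMMModel: K = %d states in P = %d dimensions\n", object@K, object@P))
  cat(sprintf("  self-transitions: %s\n",
              paste(sprintf("%.3f", diag(object@A)), collapse = " ")))
  if (length(object@freeEnergy))
    cat(sprintf("  final free energy: %.2f (%d iterations)\n",
                object@freeEnergy[length(object@freeEnergy)], length(object@freeEnergy)))
})

setMethod("show", "EpochedCourse", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochedCourse: %d trials x %d timepoints x %d states, [%.3f, %.3f] s, %d dropped\n",
              d[1], d[2], d[3], min(object@times), max(object@times), object@nDropped))
})

setMethod("show", "SpectralEstimate", function(object) {
  d <- dim(object@psd)
  cat(sprintf("SpectralEstimate '%s': %d states, %d frequencies (%.1f-%.1f Hz), %d regions\n",
              object@subjectId, d[1], d[2], min(object@freqs), max(object@freqs), d[3]))
})

setMethod("show", "SpectralModes", function(object) {
  pk <- object@freqs[apply(object@W, 2, which.max)]
  cat(sprintf("SpectralModes: %d modes over %d features; peak frequencies %s Hz; residual %.4g\n",
              ncol(object@W), ncol(object@H),
              paste(sprintf("%.1f", pk), collapse = ", "), object@residual))
})
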