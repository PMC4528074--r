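#' @rdname accessors
setMethod("values", "Timecourses", function(object) object@values)
#' @rdname accessors
setMethod("values", "EnvelopeMatrix", function(object) object@values)
#' @rdname accessors
setMethod("samplingRate", "Timecourses", function(object) object@samplingRate)
#' @rdname accessors
setMethod("samplingRate", "SimulationBundle", function(object) object@samplingRate)
#' @rdname accessors
setMethod("nodeLabels", "Timecourses", function(object) object@nodeLabels)
#' @rdname accessors
setMethod("nodeLabels", "EnvelopeMatrix", function(object) object@nodeLabels)
#' @rdname accessors
setMethod("nNodes", "Timecourses", function(object) ncol(object@values))
#' @rdname accessors
setMethod("nNodes", "EnvelopeMatrix", function(object) ncol(object@values))
#' @rdname accessors
setMethod("nNodes", "SimulationBundle", function(object) ncol(object@observed))
#' @rdname accessors
setMethod("envelopeRate", "EnvelopeMatrix", function(object) object@envelopeRate)
#' @rdname accessors
setMethod("sourceBand", "EnvelopeMatrix", function(object) object@sourceBand)

#' @rdname accessors
setMethod("orthonormalFactor", "OrthogonalisedSet", function(object) object@O)
#' @rdname accessors
setMethod("columnMagnitudes", "OrthogonalisedSet", function(object) object@d)
#' @rdname accessors
setMethod("errorTrace", "OrthogonalisedSet", function(object) object@errorTrace)
#' @rdname accessors
setMethod("isConverged", "OrthogonalisedSet", function(object) object@converged)

#' @rdname accessors
setMethod("covarianceMatrix", "NetworkEstimate", function(object) object@covariance)
#' @rdname accessors
setMethod("precisionMatrix", "NetworkEstimate", function(object) object@precision)
#' @rdname accessors
setMethod("partialCorMatrix", "NetworkEstimate", function(object) object@partialCorrelation)
#' @rdname accessors
setMethod("penalty", "NetworkEstimate", function(object) object@lambda)

#' @rdname accessors
setMethod("zMatrix", "CalibratedZ", function(object) object@z)
#' @rdname accessors
setMethod("nullSd", "CalibratedZ", function(object) object@nullSd)

#' @rdname accessors
setMethod("systemMatrix", "NetworkGroundTruth", function(object) object@A)
#' @rdname accessors
setMethod("edgeList", "NetworkGroundTruth", function(object) object@edges)
#' @rdname accessors
setMethod("observedData", "SimulationBundle", function(object) object@observed)
#' @rdname accessors
setMethod("sourceData", "SimulationBundle", function(object) object@sources)
#' @rdname accessors
setMethod("activityData", "SimulationBundle", function(object) object@activities)
#' @rdname accessors
setMethod("mixingMatrix", "SimulationBundle", function(object) object@mixing)
#' @rdname accessors
setMethod("groundTruth", "SimulationBundle", function(object) object@truth)

setMethod("show", "Timecourses", function(object) {
  v <- object@values
  cat(sprintf("%s: %d samples x %d nodes at %g Hz (%.1f s)\n", class(object),
              nrow(v), ncol(v), object@samplingRate,
              nrow(v) / object@samplingRate))
})

setMethod("show", "OrthogonalisedSet", function(object) {
  callNextMethod()
  eps <- object@errorTrace
  cat(sprintf("  tandem iterations: %d (%s); final squared error %.4g\n",
              object@iterations,
              if (object@converged) "converged" else "NOT converged",
              eps[length(eps)]))
})

setMethod("show", "EnvelopeMatrix", function(object) {
  cat(sprintf("EnvelopeMatrix: %d samples x %d nodes at %g Hz, band %g-%g Hz\n",
              nrow(object@values), ncol(object@values), object@envelopeRate,
              object@sourceBand[1], object@sourceBand[2]))
})

setMethod("show", "NetworkEstimate", function(object) {
  pc <- object@partialCorrelation
  nz <- sum(abs(pc[upper.tri(pc)]) > 1e-12)
  cat(sprintf("NetworkEstimate (%s): %d nodes, lambda = %g, %d nonzero edges\n",
              object@metric, ncol(pc), object@lambda, nz))
})

setMethod("show", "CalibratedZ", function(object) {
  cat(sprintf("CalibratedZ: %d nodes, null sd %.4g, %d subject(s), max |z| %.2f\n",
              ncol(object@z), object@nullSd, object@nSubjects,
              max(abs(object@z))))
})

setMethod("show", "NetworkGroundTruth", function(object) {
  cat(sprintf("NetworkGroundTruth: %d nodes, %d directed edges ~ N(%g, %g^2)\n",
              ncol(object@A), nrow(object@edges), object@strengthMean,
              object@strengthSd))
})

setMethod("show", "SimulationBundle", function(object) {
  cat(sprintf(paste0("SimulationBundle: %d nodes x %d samples at %g Hz; ",
                     "%d true edges, SNR %g, seed %d\n"),
              ncol(object@observed), nrow(object@observed),
              object@samplingRate, nrow(object@truth@edges), object@snr,
              object@seed))
})
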