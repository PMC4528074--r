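#' @name accessors
#' @title Accessors for leakmend classes
#'
#' @description Small accessor generics for the container classes: raw values,
#' rates, labels, the factors of an orthogonalised set, and the matrices of a
#' network estimate.
#'
#' @param object a leakmend S4 object.
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("values", function(object) standardGeneric("values"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("nodeLabels", function(object) standardGeneric("nodeLabels"))
#' @rdname accessors
#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))
#' @rdname accessors
#' @export
setGeneric("envelopeRate", function(object) standardGeneric("envelopeRate"))
#' @rdname accessors
#' @export
setGeneric("sourceBand", function(object) standardGeneric("sourceBand"))
#' @rdname accessors
#' @export
setGeneric("orthonormalFactor", function(object) standardGeneric("orthonormalFactor"))
#' @rdname accessors
#' @export
setGeneric("columnMagnitudes", function(object) standardGeneric("columnMagnitudes"))
#' @rdname accessors
#' @export
setGeneric("errorTrace", function(object) standardGeneric("errorTrace"))
#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setGeneric("covarianceMatrix", function(object) standardGeneric("covarianceMatrix"))
#' @rdname accessors
#' @export
setGeneric("precisionMatrix", function(object) standardGeneric("precisionMatrix"))
#' @rdname accessors
#' @export
setGeneric("partialCorMatrix", function(object) standardGeneric("partialCorMatrix"))
#' @rdname accessors
#' @export
setGeneric("penalty", function(object) standardGeneric("penalty"))
#' @rdname accessors
#' @export
setGeneric("zMatrix", function(object) standardGeneric("zMatrix"))
#' @rdname accessors
#' @export
setGeneric("nullSd", function(object) standardGeneric("nullSd"))
#' @rdname accessors
#' @export
setGeneric("systemMatrix", function(object) standardGeneric("systemMatrix"))
#' @rdname accessors
#' @export
setGeneric("edgeList", function(object) standardGeneric("edgeList"))
#' @rdname accessors
#' @export
setGeneric("observedData", function(object) standardGeneric("observedData"))
#' @rdname accessors
#' @export
setGeneric("sourceData", function(object) standardGeneric("sourceData"))
#' @rdname accessors
#' @export
setGeneric("activityData", function(object) standardGeneric("activityData"))
#' @rdname accessors
#' @export
setGeneric("mixingMatrix", function(object) standardGeneric("mixingMatrix"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
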