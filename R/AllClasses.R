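#' @import methods
NULL

.finiteMatrix <- function(x) is.matrix(x) && is.numeric(x) && all(is.finite(x))

#' Multichannel time-course container
#'
#' Holds a real matrix of region (node) time-courses, time samples in rows and
#' nodes in columns, together with the acquisition sampling rate and node
#' labels. The number of samples must be at least the number of nodes, the
#' regime in which a unique closest orthogonal set exists.
#'
#' @slot values numeric matrix, samples x nodes.
#' @slot samplingRate sampling rate in Hz.
#' @slot nodeLabels character vector of node identifiers, one per column.
#'
#' @seealso [Timecourses()], [symmetricOrthogonalise()]
#' @exportClass Timecourses
setClass("Timecourses",
  representation(values = "matrix", samplingRate = "numeric",
                 nodeLabels = "character"))

setValidity("Timecourses", function(object) {
  v <- object@values
  if (!.finiteMatrix(v)) return("'values' must be a finite numeric matrix")
  if (nrow(v) < ncol(v))
    return(sprintf("need at least as many samples (%d) as nodes (%d)",
                   nrow(v), ncol(v)))
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    return("'samplingRate' must be a single positive number")
  if (length(object@nodeLabels) != ncol(v))
    return("'nodeLabels' must have one entry per node")
  TRUE
})

#' Construct a Timecourses object
#'
#' @param values numeric matrix, time samples in rows, nodes in columns.
#' @param samplingRate sampling rate in Hz.
#' @param nodeLabels optional node identifiers; defaults to column names or
#'   `"node1"`, `"node2"`, ...
#' @return a [Timecourses-class] object.
#' @examples
#' tc <- Timecourses(matrix(rnorm(400), 100, 4), samplingRate = 100)
#' nNodes(tc)
#' @export
Timecourses <- function(values, samplingRate, nodeLabels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(nodeLabels)) {
    nodeLabels <- colnames(values)
    if (is.null(nodeLabels)) nodeLabels <- paste0("node", seq_len(ncol(values)))
  }
  colnames(values) <- nodeLabels
  new("Timecourses", values = values, samplingRate = as.numeric(samplingRate),
      nodeLabels = as.character(nodeLabels))
}

#' Result of the symmetric (tandem) orthogonalisation
#'
#' Extends [Timecourses-class]: `values` holds the corrected time-courses
#' P = O diag(d), where O is orthonormal and d the fitted column magnitudes.
#' The error trace records the squared Frobenius distance to the uncorrected
#' input after every iteration of the tandem algorithm.
#'
#' @slot O orthonormal matrix, samples x nodes.
#' @slot d positive column magnitudes.
#' @slot errorTrace per-iteration squared Frobenius reconstruction error.
#' @slot iterations number of tandem iterations performed.
#' @slot converged whether the stopping rule was met within the iteration cap.
#' @exportClass OrthogonalisedSet
setClass("OrthogonalisedSet", contains = "Timecourses",
  representation(O = "matrix", d = "numeric", errorTrace = "numeric",
                 iterations = "integer", converged = "logical"))

setValidity("OrthogonalisedSet", function(object) {
  n <- ncol(object@values)
  if (!identical(dim(object@O), dim(object@values)))
    return("'O' must match the shape of 'values'")
  if (length(object@d) != n) return("'d' must have one magnitude per node")
  if (any(object@d <= 0)) return("column magnitudes 'd' must be positive")
  if (length(object@converged) != 1L) return("'converged' must be a flag")
  TRUE
})

#' Band-limited power envelopes
#'
#' Low-pass-filtered, downsampled Hilbert amplitude envelopes of a set of
#' node time-courses; rows are envelope samples (default rate 1 Hz), columns
#' nodes.
#'
#' @slot values numeric matrix, envelope samples x nodes.
#' @slot envelopeRate envelope sampling rate in Hz.
#' @slot sourceBand the band (Hz) the carriers were filtered to, `c(low, high)`.
#' @slot nodeLabels node identifiers.
#' @exportClass EnvelopeMatrix
setClass("EnvelopeMatrix",
  representation(values = "matrix", envelopeRate = "numeric",
                 sourceBand = "numeric", nodeLabels = "character"))

setValidity("EnvelopeMatrix", function(object) {
  if (!.finiteMatrix(object@values)) return("'values' must be finite numeric")
  if (length(object@envelopeRate) != 1L || object@envelopeRate <= 0)
    return("'envelopeRate' must be a single positive number")
  if (length(object@sourceBand) != 2L || object@sourceBand[1] >= object@sourceBand[2])
    return("'sourceBand' must be c(low, high) with low < high")
  if (length(object@nodeLabels) != ncol(object@values))
    return("'nodeLabels' must have one entry per node")
  TRUE
})

#' Network estimate from envelope data
#'
#' Covariance, precision and partial-correlation matrices for a set of nodes,
#' with the L1 penalty used (0 for unregularised fits) and the connectivity
#' metric the estimate corresponds to.
#'
#' @slot covariance n x n sample covariance.
#' @slot precision n x n (possibly regularised) precision matrix.
#' @slot partialCorrelation n x n partial correlations, unit diagonal.
#' @slot lambda L1 penalty strength used for `precision`.
#' @slot metric one of `"full"`, `"partial"`, `"partial_regularised"`.
#' @exportClass NetworkEstimate
setClass("NetworkEstimate",
  representation(covariance = "matrix", precision = "matrix",
                 partialCorrelation = "matrix", lambda = "numeric",
                 metric = "character"))

setValidity("NetworkEstimate", function(object) {
  n <- ncol(object@covariance)
  if (!identical(dim(object@precision), c(n, n)) ||
      !identical(dim(object@partialCorrelation), c(n, n)))
    return("matrix slots must share one n x n shape")
  pc <- object@partialCorrelation
  if (any(is.finite(pc) & abs(pc) > 1 + 1e-8))
    return("partial correlations must lie in [-1, 1]")
  if (length(object@lambda) != 1L || object@lambda < 0)
    return("'lambda' must be a single nonnegative number")
  if (!object@metric %in% c("full", "partial", "partial_regularised"))
    return("unknown metric")
  TRUE
})

#' Calibrated edge Z-scores
#'
#' Fisher-transformed edge correlations scaled by the standard deviation of an
#' empirical null distribution, so that edge scores are standard normal when
#' there is no connectivity.
#'
#' @slot z n x n symmetric matrix of calibrated scores, zero diagonal.
#' @slot nullSd the empirical-null standard deviation used for scaling.
#' @slot nSubjects number of subjects pooled into this matrix (1 = single run).
#' @exportClass CalibratedZ
setClass("CalibratedZ",
  representation(z = "matrix", nullSd = "numeric", nSubjects = "integer"))

setValidity("CalibratedZ", function(object) {
  z <- object@z
  if (!.finiteMatrix(z) || nrow(z) != ncol(z)) return("'z' must be finite and square")
  if (max(abs(z - t(z))) > 1e-8) return("'z' must be symmetric")
  if (length(object@nullSd) != 1L || object@nullSd <= 0)
    return("'nullSd' must be a single positive number")
  TRUE
})

#' Ground-truth network for the simulator
#'
#' System matrix A of the linear stochastic network model: diagonal entries
#' are -1 (within-node temporal decay) and nonzero off-diagonal entries, at
#' exactly the requested directed edges, are the sampled coupling strengths.
#'
#' @slot A n x n system matrix.
#' @slot edges integer matrix, k x 2, directed edges as (from, to) rows.
#' @slot strengthMean,strengthSd the normal distribution edge weights were
#'   drawn from.
#' @exportClass NetworkGroundTruth
setClass("NetworkGroundTruth",
  representation(A = "matrix", edges = "matrix",
                 strengthMean = "numeric", strengthSd = "numeric"))

setValidity("NetworkGroundTruth", function(object) {
  A <- object@A
  if (nrow(A) != ncol(A)) return("'A' must be square")
  if (any(diag(A) != -1)) return("diagonal of 'A' must be -1")
  off <- which(A != 0 & row(A) != col(A), arr.ind = TRUE)
  want <- object@edges[, c(2L, 1L), drop = FALSE] # A[to, from]
  if (nrow(off) != nrow(want)) return("nonzero off-diagonals must match edges")
  key <- function(m) sort(paste(m[, 1], m[, 2]))
  if (!identical(key(off), key(want))) return("edge positions disagree with 'A'")
  TRUE
})

#' Binary Poisson burst drive
#'
#' Alternating-renewal on/off input processes, one per node: exponentially
#' distributed on and off durations, value `strength` while on and 0 while
#' off.
#'
#' @slot u samples x nodes drive matrix, values in \{0, strength\}.
#' @slot strength drive amplitude while on.
#' @slot meanOn,meanOff mean on/off durations in seconds.
#' @slot dt time step of the discretised process in seconds.
#' @exportClass DriveProcess
setClass("DriveProcess",
  representation(u = "matrix", strength = "numeric", meanOn = "numeric",
                 meanOff = "numeric", dt = "numeric"))

setValidity("DriveProcess", function(object) {
  vals <- unique(as.vector(object@u))
  if (!all(vals %in% c(0, object@strength)))
    return("drive values must be 0 or 'strength'")
  TRUE
})

#' One simulated experiment
#'
#' Node activities from the network model, modulated carrier sources, and the
#' observed signals after zero-lag linear mixing (the leakage stand-in) plus
#' additive Gaussian noise at the requested signal-to-noise power ratio.
#'
#' @slot truth the [NetworkGroundTruth-class] used.
#' @slot activities samples x nodes amplitude ("functional activity") matrix.
#' @slot sources samples x nodes modulated carrier oscillations.
#' @slot observed samples x nodes observed (mixed + noisy) signals.
#' @slot mixing n x n row-stochastic zero-lag mixing matrix.
#' @slot carriers carrier frequency (Hz) per node.
#' @slot noiseSd standard deviation of the added observation noise.
#' @slot snr requested mean-square-signal / noise-variance power ratio.
#' @slot samplingRate sampling rate (Hz) of all three signal matrices.
#' @slot seed integer seed the bundle was generated from.
#' @exportClass SimulationBundle
setClass("SimulationBundle",
  representation(truth = "NetworkGroundTruth", activities = "matrix",
                 sources = "matrix", observed = "matrix", mixing = "matrix",
                 carriers = "numeric", noiseSd = "numeric", snr = "numeric",
                 samplingRate = "numeric", seed = "integer"))

setValidity("SimulationBundle", function(object) {
  n <- ncol(object@observed)
  if (ncol(object@sources) != n || ncol(object@activities) != n)
    return("activities, sources and observed must share a node count")
  if (!identical(dim(object@mixing), c(n, n)))
    return("'mixing' must be n x n")
  if (any(object@mixing < 0) || max(abs(rowSums(object@mixing) - 1)) > 1e-8)
    return("'mixing' must be nonnegative with unit row sums")
  if (length(object@carriers) != n || anyDuplicated(object@carriers))
    return("'carriers' must give one distinct frequency per node")
  TRUE
})
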