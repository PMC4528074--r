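#' Closest orthonormal matrix (symmetric / Loewdin orthogonalisation)
#'
#' Finds the unique orthonormal matrix closest, in the Frobenius norm, to a
#' full-column-rank matrix `Z`: the polar factor `O = U V'` of the singular
#' value decomposition `Z = U diag(sigma) V'`. Applied to a set of node
#' time-courses this removes every zero-lag correlation while also forcing
#' all columns to unit norm; [symmetricOrthogonalise()] relaxes the norm
#' constraint.
#'
#' @param Z a [Timecourses-class] object or a numeric matrix with at least as
#'   many rows (samples) as columns (nodes).
#' @param rankTolerance declare rank deficiency when the ratio of smallest to
#'   largest singular value falls below this (default `1e-10`, the double
#'   precision SVD noise floor).
#' @return the orthonormal matrix `O` (plain matrix, same shape as `Z`).
#' @examples
#' Z <- matrix(rnorm(60), 20, 3)
#' O <- closestOrthonormal(Z)
#' max(abs(crossprod(O) - diag(3))) # ~ 1e-15
#' @export
closestOrthonormal <- function(Z, rankTolerance = 1e-10) {
  Z <- .asValuesMatrix(Z)
  if (nrow(Z) < ncol(Z))
    stop("'Z' must have at least as many samples (rows) as nodes (columns): ",
         nrow(Z), " x ", ncol(Z))
  sv <- svd(Z, nu = ncol(Z), nv = ncol(Z))
  ratio <- sv$d[length(sv$d)] / sv$d[1]
  if (!is.finite(ratio) || ratio < rankTolerance)
    stop(sprintf(paste0("rank-deficient input: smallest/largest singular ",
                        "value ratio %.3g is below the rank tolerance %.3g"),
                 ratio, rankTolerance))
  sv$u %*% t(sv$v)
}

#' Symmetric multivariate leakage correction (tandem algorithm)
#'
#' Removes all zero-lag correlations among `n` node time-courses by finding
#' the set of mutually *orthogonal* (not orthonormal) vectors `P = O diag(d)`
#' closest to the originals in the least-squares sense. The solution is
#' unique up to the usual local-minimum caveat, is unchanged by any
#' reordering of the nodes, and displaces the time-courses minimally, which
#' makes it the natural multivariate correction for zero-lag mixing
#' ("leakage") among reconstructed signals.
#'
#' The tandem iteration alternates two closed-form updates, starting from
#' `D = I` (so the first orthonormal factor is the Loewdin orthogonalisation
#' of `Z` itself):
#' \enumerate{
#'   \item `O <- closestOrthonormal(Z D)` (polar factor of `Z D`),
#'   \item `d <- diag(Z' O)` (the least-squares column magnitudes).
#' }
#' Each step cannot increase the squared Frobenius error
#' `eps = ||Z - O diag(d)||_F^2`, so the error trace is non-increasing and the
#' iteration converges — though not necessarily to the global minimum.
#' Iteration stops when the change in `eps` relative to `||Z||_F^2` falls
#' below `tolerance`; typical inputs converge well within twenty iterations.
#'
#' @param Z a [Timecourses-class] object or numeric matrix (samples x nodes),
#'   full column rank, at least as many samples as nodes.
#' @param tolerance scale-free stopping threshold on
#'   `|eps_k - eps_(k-1)| / ||Z||_F^2` (default `1e-10`).
#' @param maxIterations iteration cap (default 50). Hitting the cap flags the
#'   result as not converged rather than raising an error, so batch runs can
#'   continue.
#' @param rankTolerance passed to [closestOrthonormal()].
#' @return an [OrthogonalisedSet-class]; its `values` slot holds the
#'   corrected time-courses `P`.
#' @examples
#' set.seed(1)
#' Z <- matrix(rnorm(2000), 500, 4)
#' Z[, 2] <- Z[, 2] + 0.7 * Z[, 1] # induce zero-lag correlation
#' os <- symmetricOrthogonalise(Z)
#' max(abs(cor(values(os))[upper.tri(diag(4))])) # ~ 0
#' @export
symmetricOrthogonalise <- function(Z, tolerance = 1e-10, maxIterations = 50L,
                                   rankTolerance = 1e-10) {
  rate <- if (is(Z, "Timecourses")) Z@samplingRate else 1
  labels <- if (is(Z, "Timecourses")) Z@nodeLabels else NULL
  Z <- .asValuesMatrix(Z)
  n <- ncol(Z)
  scale2 <- sum(Z^2)
  d <- rep(1, n)
  errTrace <- numeric(0)
  lastErr <- Inf
  converged <- FALSE
  iter <- 0L
  O <- NULL
  repeat {
    iter <- iter + 1L
    O <- closestOrthonormal(Z %*% diag(d, n), rankTolerance = rankTolerance)
    d <- colSums(Z * O)
    err <- scale2 - sum(d^2) # trace(Z'Z) - 2 trace(Z'OD) + trace(D^2) at d = diag(Z'O)
    errTrace <- c(errTrace, err)
    if (is.finite(lastErr) && abs(lastErr - err) / scale2 < tolerance) {
      converged <- TRUE
      break
    }
    if (iter >= maxIterations) break
    lastErr <- err
  }
  if (converged && any(d <= 0))
    stop("degenerate geometry: a fitted column magnitude is non-positive; ",
         "the closest orthogonal set is not well defined for this input")
  P <- O %*% diag(d, n)
  if (is.null(labels)) labels <- paste0("node", seq_len(n))
  colnames(P) <- labels
  new("OrthogonalisedSet", values = P, samplingRate = rate,
      nodeLabels = labels, O = O, d = d, errorTrace = errTrace,
      iterations = iter, converged = converged)
}

#' Squared Frobenius reconstruction error
#'
#' The squared Frobenius distance `trace((Z - P)'(Z - P))` between the
#' uncorrected time-courses and a candidate corrected set — the quantity the
#' tandem algorithm minimises.
#'
#' @param Z,P numeric matrices (or [Timecourses-class]) of identical shape.
#' @return a single nonnegative number.
#' @export
reconstructionError <- function(Z, P) {
  Z <- .asValuesMatrix(Z)
  P <- .asValuesMatrix(P)
  if (!identical(dim(Z), dim(P)))
    stop("'Z' and 'P' must have identical shapes: ",
         paste(dim(Z), collapse = "x"), " vs ", paste(dim(P), collapse = "x"))
  sum((Z - P)^2)
}

#' Pair-wise orthogonalisation of two time-courses
#'
#' The bivariate leakage correction used by seed-based analyses: each signal
#' is regressed out of the other, yielding two residual series, each exactly
#' orthogonal to its seed. Unlike the symmetric correction the outcome
#' depends on which signal is treated as the seed, which is why downstream
#' comparisons average over both choices.
#'
#' @param x,y numeric vectors of equal length (>= 2), neither identically
#'   zero.
#' @param tolerance collinearity guard: inputs with `|cor(x, y)|` above
#'   `1 - tolerance` are rejected as a degenerate pair (default `1e-10`).
#' @return a list with `yGivenX` (residual of `y` after regressing out `x`)
#'   and `xGivenY` (residual of `x` after regressing out `y`).
#' @export
pairwiseOrthogonalise <- function(x, y, tolerance = 1e-10) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 2L)
    stop("'x' and 'y' must be vectors of equal length >= 2")
  nx2 <- sum(x^2); ny2 <- sum(y^2)
  if (nx2 == 0 || ny2 == 0) stop("inputs must not be identically zero")
  xy <- sum(x * y)
  cosine2 <- xy^2 / (nx2 * ny2)
  if (cosine2 > (1 - tolerance)^2)
    stop(sprintf("degenerate pair: inputs are collinear (|cosine| = %.12f)",
                 sqrt(cosine2)))
  list(yGivenX = y - x * (xy / nx2),
       xGivenY = x - y * (xy / ny2))
}

# Coerce Timecourses / EnvelopeMatrix / matrix-like to a double matrix.
.asValuesMatrix <- function(x) {
  if (is(x, "Timecourses") || is(x, "EnvelopeMatrix")) x <- x@values
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("input values must all be finite")
  x
}
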