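#' Partial correlations from a precision matrix
#'
#' Converts a symmetric precision (inverse covariance) matrix into the
#' partial-correlation matrix: the correlation between each pair of
#' variables with the linear effect of all other variables removed,
#' `rho_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)`, with unit diagonal by
#' convention. Zeros identify conditionally independent pairs, i.e. absent
#' edges in the Gaussian graphical model.
#'
#' @param omega symmetric numeric matrix with strictly positive diagonal.
#' @return the partial-correlation matrix.
#' @examples
#' partialCorrelation(matrix(c(1, -0.5, -0.5, 1), 2)) # off-diagonal 0.5
#' @export
partialCorrelation <- function(omega) {
  omega <- as.matrix(omega)
  if (nrow(omega) != ncol(omega) || max(abs(omega - t(omega))) > 1e-8)
    stop("'omega' must be a symmetric square matrix")
  d <- diag(omega)
  if (any(d <= 0)) stop("'omega' must have a strictly positive diagonal")
  s <- 1 / sqrt(d)
  rho <- -omega * tcrossprod(s)
  diag(rho) <- 1
  rho
}

#' L1-regularised precision estimation (graphical lasso)
#'
#' Maximises `log det(Omega) - tr(S Omega) - lambda * ||Omega||_1` over
#' positive-definite matrices by block coordinate descent on the working
#' covariance. By default the penalty covers the whole matrix including the
#' diagonal; set `penalizeDiagonal = FALSE` for the off-diagonal-only
#' convention common in other implementations. At `lambda = 0` the solution
#' is the unpenalised maximum-likelihood precision, `solve(S)`.
#'
#' @param S symmetric positive semi-definite covariance (or correlation)
#'   matrix; must be positive definite when `lambda = 0`.
#' @param lambda nonnegative penalty strength.
#' @param penalizeDiagonal include the diagonal in the L1 penalty
#'   (default TRUE).
#' @param tol convergence tolerance on the working covariance, relative to
#'   the mean absolute off-diagonal of `S`.
#' @param maxit cap on outer sweeps; non-convergence raises an error
#'   reporting the attained duality gap.
#' @return the estimated precision matrix, with attributes `"gap"` (duality
#'   gap) and `"sweeps"`.
#' @export
graphicalLasso <- function(S, lambda, penalizeDiagonal = TRUE, tol = 1e-7,
                           maxit = 200L) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8)
    stop("'S' must be a symmetric square matrix")
  if (lambda < 0) stop("'lambda' must be nonnegative")
  if (lambda == 0) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12 * max(ev))
      stop("'S' is singular; lambda > 0 is required")
    theta <- chol2inv(chol(S))
    dimnames(theta) <- dimnames(S)
    attr(theta, "gap") <- 0
    attr(theta, "sweeps") <- 0L
    return(theta)
  }
  fit <- glasso_cpp(S, lambda, penalizeDiagonal, tol, as.integer(maxit), 2000L)
  if (!fit$converged)
    stop(sprintf("graphical lasso did not converge in %d sweeps (duality gap %.3g)",
                 maxit, fit$gap))
  theta <- fit$theta
  dimnames(theta) <- dimnames(S)
  attr(theta, "gap") <- fit$gap
  attr(theta, "sweeps") <- fit$sweeps
  theta
}

#' Cross-validated penalty selection by held-out AICc
#'
#' Chooses the graphical-lasso penalty by 10-fold cross-validation on
#' contiguous temporal blocks (envelopes are autocorrelated, so random folds
#' would leak information between training and validation). For each grid
#' value the model is fitted on the training blocks and scored on the
#' held-out block with the corrected Akaike information criterion,
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n_val - k - 1)`, where the effective
#' parameter count `k` is the number of nodes plus the number of nonzero
#' upper-triangle precision entries. The grid (16 points, geometric over
#' `gridRange`) is then zoomed by a factor of four around the incumbent,
#' `refinements` times.
#'
#' @param envelopes an [EnvelopeMatrix-class], [Timecourses-class] or plain
#'   matrix (samples x nodes).
#' @param folds number of contiguous cross-validation blocks (default 10);
#'   every fold needs at least 5 samples.
#' @param refinements number of grid zooms (default 3); with 0 the returned
#'   value is a member of the initial grid.
#' @param gridSize points per grid (default 16).
#' @param gridRange initial geometric grid limits (default `c(1e-4, 1)`).
#' @param penalizeDiagonal passed to [graphicalLasso()].
#' @return the selected lambda, with attribute `"aicc"` (its summed
#'   held-out score).
#' @export
selectLambda <- function(envelopes, folds = 10L, refinements = 3L,
                         gridSize = 16L, gridRange = c(1e-4, 1),
                         penalizeDiagonal = TRUE) {
  X <- .asValuesMatrix(envelopes)
  m <- nrow(X)
  n <- ncol(X)
  if (m < 5L * folds)
    stop(sprintf("need at least 5 samples per fold: %d samples, %d folds", m, folds))
  X <- scale(X) # partial correlations are scale-free; a common scale keeps
                # lambda comparable across datasets
  foldId <- cut(seq_len(m), breaks = folds, labels = FALSE)
  sdOk <- vapply(seq_len(folds), function(f) {
    all(apply(X[foldId != f, , drop = FALSE], 2L, stats::sd) > 0)
  }, logical(1))
  if (!any(sdOk)) stop("all folds have degenerate variance")
  if (!all(sdOk)) warning(sum(!sdOk), " fold(s) skipped for degenerate variance")

  score <- function(lambda) {
    ll <- 0
    kSum <- 0
    nVal <- 0
    for (f in which(sdOk)) {
      tr <- X[foldId != f, , drop = FALSE]
      va <- X[foldId == f, , drop = FALSE]
      Str <- crossprod(tr) / nrow(tr)
      Sva <- crossprod(va) / nrow(va)
      theta <- try(graphicalLasso(Str, lambda,
                                  penalizeDiagonal = penalizeDiagonal),
                   silent = TRUE)
      if (inherits(theta, "try-error")) return(Inf)
      ldet <- determinant(theta, logarithm = TRUE)
      if (ldet$sign <= 0) return(Inf)
      ll <- ll + (nrow(va) / 2) * (as.numeric(ldet$modulus) -
                                   sum(Sva * theta) - n * log(2 * pi))
      kSum <- kSum + n + sum(abs(theta[upper.tri(theta)]) > 1e-10)
      nVal <- nVal + nrow(va)
    }
    # held-out log-likelihood pooled over folds; AICc small-sample correction
    # applied at the pooled validation size with the mean support size
    k <- kSum / sum(sdOk)
    if (nVal - k - 1 <= 0) return(Inf) # AICc undefined: model richer than data
    -2 * ll + 2 * k + 2 * k * (k + 1) / (nVal - k - 1)
  }

  grid <- exp(seq(log(gridRange[1]), log(gridRange[2]), length.out = gridSize))
  best <- NA_real_
  bestScore <- Inf
  for (round in 0:refinements) {
    if (round > 0)
      grid <- exp(seq(log(best / 4), log(best * 4), length.out = gridSize))
    sc <- vapply(grid, score, numeric(1))
    if (all(!is.finite(sc)))
      sc[length(sc)] <- .Machine$double.xmax # fall back to the sparsest fit
    i <- which.min(sc)
    if (sc[i] <= bestScore) {
      best <- grid[i]
      bestScore <- sc[i]
    }
  }
  attr(best, "aicc") <- bestScore
  best
}

#' Fisher's variance-stabilising transform
#'
#' `fisherZ(r) = atanh(r)`, mapping correlations in (-1, 1) to the real
#' line; antisymmetric in `r`.
#'
#' @param r correlation value(s), all strictly inside (-1, 1).
#' @return transformed value(s) of the same shape.
#' @export
fisherZ <- function(r) {
  if (any(abs(r) >= 1)) stop("Fisher transform requires |r| < 1")
  atanh(r)
}

#' Empirical-null scaling for edge scores
#'
#' Estimates the standard deviation of Fisher-transformed edge correlations
#' under the null of no connectivity, accounting for the temporal smoothness
#' of the power envelopes (slow amplitude dynamics inflate the sampling
#' variability of envelope correlations well beyond the white-noise
#' `1/sqrt(m - 3)`). Draws `nNull` surrogate datasets of independent
#' stationary AR(1) series matched in node count, sample count and lag-1
#' autocorrelation to the envelopes under analysis, computes all edge
#' correlations (or unregularised partial correlations), Fisher-transforms
#' them, and returns the pooled standard deviation. Dividing observed edge
#' z-values by this scaling makes them standard normal under the null.
#'
#' @param nNodes number of nodes.
#' @param nEnvelopeSamples number of envelope samples being matched.
#' @param ar1 lag-1 autocorrelation of the envelopes (`|ar1| < 1`); see
#'   [envelopeAr1()].
#' @param metric `"full"` for correlations, `"partial"` for unregularised
#'   partial correlations.
#' @param nNull number of null datasets (>= 20; default 50).
#' @param seed integer seed for the null draws.
#' @return the pooled null standard deviation (positive scalar).
#' @export
nullScaling <- function(nNodes, nEnvelopeSamples, ar1,
                        metric = c("full", "partial"), nNull = 50L,
                        seed = 1L) {
  metric <- match.arg(metric)
  if (nNull < 20L) stop("'nNull' must be at least 20")
  if (abs(ar1) >= 1) stop("'ar1' must satisfy |ar1| < 1")
  pooled <- vector("list", nNull)
  for (i in seq_len(nNull)) {
    X <- ar1Null(nNodes, nEnvelopeSamples, phi = ar1,
                 seed = seed + i)@values
    r <- if (metric == "full") {
      stats::cor(X)
    } else {
      partialCorrelation(solve(stats::cov(X)))
    }
    pooled[[i]] <- fisherZ(r[upper.tri(r)])
  }
  stats::sd(unlist(pooled))
}

#' Mean lag-1 autocorrelation of a set of envelopes
#'
#' The temporal-smoothness summary used to match the AR(1) surrogates in
#' [nullScaling()]: the lag-1 sample autocorrelation of each node's
#' envelope, averaged over nodes.
#'
#' @param envelopes an [EnvelopeMatrix-class] or matrix (samples x nodes).
#' @return a single number in (-1, 1).
#' @export
envelopeAr1 <- function(envelopes) {
  X <- .asValuesMatrix(envelopes)
  mean(apply(X, 2L, function(x) stats::cor(x[-1L], x[-length(x)])))
}

#' Estimate a network from power envelopes
#'
#' Computes the sample covariance of the envelopes and the requested
#' connectivity metric: full correlation, unregularised partial correlation
#' (from the inverted covariance), or L1-regularised partial correlation
#' (from the graphical-lasso precision at `lambda`, selected by
#' [selectLambda()] when not supplied).
#'
#' @param envelopes an [EnvelopeMatrix-class] (or matrix, samples x nodes).
#' @param metric one of `"full"`, `"partial"`, `"partial_regularised"`.
#' @param lambda penalty for the regularised metric; `NULL` (default)
#'   selects it by cross-validated AICc.
#' @param penalizeDiagonal passed to [graphicalLasso()].
#' @return a [NetworkEstimate-class].
#' @export
networkEstimate <- function(envelopes,
                            metric = c("full", "partial", "partial_regularised"),
                            lambda = NULL, penalizeDiagonal = TRUE) {
  metric <- match.arg(metric)
  X <- .asValuesMatrix(envelopes)
  S <- stats::cov(X)
  R <- stats::cor(X)
  if (metric == "full") {
    omega <- chol2inv(chol(R))
    rho <- R
    diag(rho) <- 1
    lambda <- 0
  } else if (metric == "partial") {
    omega <- chol2inv(chol(R))
    rho <- partialCorrelation(omega)
    lambda <- 0
  } else {
    if (is.null(lambda)) lambda <- as.numeric(selectLambda(X,
        penalizeDiagonal = penalizeDiagonal))
    omega <- graphicalLasso(R, lambda, penalizeDiagonal = penalizeDiagonal)
    attributes(omega)[c("gap", "sweeps")] <- NULL
    rho <- partialCorrelation(omega)
  }
  rho <- pmin(pmax(rho, -1), 1)
  new("NetworkEstimate", covariance = S, precision = omega,
      partialCorrelation = rho, lambda = as.numeric(lambda), metric = metric)
}

#' Calibrate edge scores against an empirical null
#'
#' Fisher-transforms the edge values of a network estimate and divides by
#' the empirical-null standard deviation (see [nullScaling()]), yielding
#' scores that are standard normal under the no-connectivity null.
#'
#' @param estimate a [NetworkEstimate-class], or a plain symmetric
#'   correlation matrix.
#' @param nullSd positive null scaling.
#' @return a [CalibratedZ-class] with zero diagonal.
#' @export
calibrateZ <- function(estimate, nullSd) {
  r <- if (is(estimate, "NetworkEstimate")) {
    switch(estimate@metric,
           full = stats::cov2cor(estimate@covariance),
           estimate@partialCorrelation)
  } else as.matrix(estimate)
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z <- fisherZ(r) / nullSd
  diag(z) <- 0
  z <- (z + t(z)) / 2
  new("CalibratedZ", z = z, nullSd = as.numeric(nullSd), nSubjects = 1L)
}

#' Fixed-effects group inference on edge scores
#'
#' Tests the group-mean effect at every edge: given calibrated per-subject
#' matrices `z_1 ... z_S` the group score is `sum(z_i) / sqrt(S)`, which is
#' standard normal under the null at every edge.
#'
#' @param zStack list of [CalibratedZ-class] objects with matching shapes.
#' @return a [CalibratedZ-class] with `nSubjects = S`.
#' @export
groupFixedEffects <- function(zStack) {
  if (is(zStack, "CalibratedZ")) zStack <- list(zStack)
  S <- length(zStack)
  if (S < 1L) stop("need at least one subject")
  dims <- lapply(zStack, function(cz) dim(cz@z))
  if (length(unique(dims)) != 1L) stop("subject z matrices differ in shape")
  zSum <- Reduce(`+`, lapply(zStack, zMatrix))
  new("CalibratedZ", z = zSum / sqrt(S),
      nullSd = mean(vapply(zStack, nullSd, numeric(1))),
      nSubjects = as.integer(S))
}

#' Benjamini-Hochberg step-up rejection
#'
#' The step-up rule at level `q`: sort the p-values, find the largest `i`
#' with `p(i) <= i q / m`, and reject everything at or below it.
#'
#' @param p vector of p-values.
#' @param q target false discovery rate in (0, 1).
#' @return logical vector, `TRUE` where rejected.
#' @examples
#' sum(bhReject(c(0.001, 0.02, 0.04, 0.8), 0.05)) # 2
#' @export
bhReject <- function(p, q = 0.05) {
  stats::p.adjust(p, method = "BH") <= q
}

#' False-discovery-rate edge threshold
#'
#' One-sided test for positive edges: upper-triangle z-scores are converted
#' to p-values `1 - pnorm(z)` and controlled with the Benjamini-Hochberg
#' step-up procedure at rate `q`. Returns the implied z threshold (the
#' smallest surviving score; `Inf` when nothing survives) and the binary
#' edge mask.
#'
#' @param z a [CalibratedZ-class] or symmetric numeric matrix.
#' @param q target false discovery rate in (0, 1), default 0.05.
#' @return list with `threshold` (scalar) and `mask` (symmetric logical
#'   matrix, `TRUE` for surviving edges).
#' @export
fdrThreshold <- function(z, q = 0.05) {
  if (q <= 0 || q >= 1) stop("'q' must lie in (0, 1)")
  zm <- if (is(z, "CalibratedZ")) z@z else as.matrix(z)
  ut <- upper.tri(zm)
  p <- stats::pnorm(zm[ut], lower.tail = FALSE)
  keep <- bhReject(p, q)
  mask <- matrix(FALSE, nrow(zm), ncol(zm), dimnames = dimnames(zm))
  mask[ut] <- keep
  mask <- mask | t(mask)
  threshold <- if (any(keep)) min(zm[ut][keep]) else Inf
  list(threshold = threshold, mask = mask)
}
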