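# Independent oracles used by the unit and acceptance tests. Each is a
# deliberately naive route to the same quantity as the implementation under
# test: direct formulas, element loops, eigen decompositions, or a
# first-order proximal-gradient solver. None shares code with R/.

# Polar factor via the inverse matrix square root: Z (Z'Z)^(-1/2),
# computed by eigendecomposition of the Gram matrix.
polarOracle <- function(Z) {
  G <- crossprod(Z)
  e <- eigen(G, symmetric = TRUE)
  Z %*% (e$vectors %*% diag(1 / sqrt(e$values), ncol(Z)) %*% t(e$vectors))
}

# Classical Gram-Schmidt "correction": each column is replaced by its
# residual against the span of the previously corrected columns (magnitudes
# kept). Returns the squared Frobenius displacement from Z for the given
# column ordering.
gramSchmidtError <- function(Z, ordering = seq_len(ncol(Z))) {
  P <- Z
  basis <- NULL
  for (j in ordering) {
    v <- Z[, j]
    if (!is.null(basis)) {
      coefs <- crossprod(basis, v)
      v <- v - basis %*% coefs
    }
    P[, j] <- v
    b <- v / sqrt(sum(v^2))
    basis <- cbind(basis, b)
  }
  sum((Z - P)^2)
}

# Element-loop squared-difference sum (reconstruction-error oracle).
frobeniusLoop <- function(A, B) {
  tot <- 0
  for (i in seq_len(nrow(A)))
    for (j in seq_len(ncol(A)))
      tot <- tot + (A[i, j] - B[i, j])^2
  tot
}

# Partial correlation of variables i and j given the rest, by explicit
# residualisation: correlate the residuals of i and j after regressing out
# all remaining columns.
residualPartialCor <- function(X, i, j) {
  others <- X[, -c(i, j), drop = FALSE]
  if (ncol(others) == 0) return(stats::cor(X[, i], X[, j]))
  others <- cbind(1, others)
  ri <- stats::lm.fit(others, X[, i])$residuals
  rj <- stats::lm.fit(others, X[, j])$residuals
  stats::cor(ri, rj)
}

# Graphical-lasso objective (to be MINIMISED): -logdet + tr(S Om) + lambda*pen.
glassoObjective <- function(Omega, S, lambda, penalizeDiagonal = TRUE) {
  pen <- sum(abs(Omega)) - if (penalizeDiagonal) 0 else sum(abs(diag(Omega)))
  ld <- determinant(Omega, logarithm = TRUE)
  if (ld$sign <= 0) return(Inf)
  -as.numeric(ld$modulus) + sum(S * Omega) + lambda * pen
}

# Independent first-order solver for the graphical lasso: proximal gradient
# (ISTA) with backtracking on the penalised negative log-likelihood. Slow
# and simple; used only on small instances.
istaGlasso <- function(S, lambda, penalizeDiagonal = TRUE, maxit = 20000,
                       tol = 1e-12) {
  n <- ncol(S)
  Omega <- diag(1 / diag(S))
  step <- 0.1
  obj <- glassoObjective(Omega, S, lambda, penalizeDiagonal)
  for (it in seq_len(maxit)) {
    grad <- S - solve(Omega) # gradient of the smooth part
    repeat {
      cand <- Omega - step * grad
      thr <- step * lambda
      softened <- sign(cand) * pmax(abs(cand) - thr, 0)
      if (!penalizeDiagonal) diag(softened) <- diag(cand)
      softened <- (softened + t(softened)) / 2
      newObj <- glassoObjective(softened, S, lambda, penalizeDiagonal)
      if (is.finite(newObj) && newObj <= obj + 1e-15) break
      step <- step / 2
      if (step < 1e-12) return(list(omega = Omega, objective = obj))
    }
    delta <- obj - newObj
    Omega <- softened
    obj <- newObj
    step <- step * 1.25
    if (delta < tol && it > 10) break
  }
  list(omega = Omega, objective = obj)
}

# Random symmetric positive-definite matrix with unit-ish diagonal.
randomSpd <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  S <- crossprod(A) / n + 0.5 * diag(n)
  stats::cov2cor(S)
}

# Random full-column-rank matrix with bounded condition number.
randomFullRank <- function(m, n, seed, maxCondition = 50) {
  set.seed(seed)
  repeat {
    Z <- matrix(rnorm(m * n), m, n)
    d <- svd(Z, nu = 0, nv = 0)$d
    if (d[1] / d[n] < maxCondition) return(Z)
  }
}
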