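test_that("partialCorrelation matches direct substitution and the residualisation oracle", {
  expect_equal(partialCorrelation(diag(3)), diag(3))
  expect_equal(partialCorrelation(matrix(c(1, -0.5, -0.5, 1), 2))[1, 2], 0.5)

  # 3-variable chain: compare against explicit regression residuals
  set.seed(8)
  x <- rnorm(5000)
  y <- 0.7 * x + rnorm(5000, sd = 0.5)
  z <- 0.6 * y + rnorm(5000, sd = 0.5)
  X <- cbind(x, y, z)
  Omega <- solve(stats::cov(X))
  rho <- partialCorrelation(Omega)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    expect_equal(rho[pair[1], pair[2]],
                 residualPartialCor(X, pair[1], pair[2]), tolerance = 1e-8)
  }

  expect_error(partialCorrelation(matrix(c(-1, 0, 0, 1), 2)), "positive diagonal")
  expect_error(partialCorrelation(matrix(1:6, 2, 3)), "square")
})

test_that("partialCorrelation agrees with residualisation for arbitrary SPD covariances", {
  for (seed in 1:8) {
    n <- sample(3:6, 1)
    S <- randomSpd(n, seed)
    set.seed(seed + 100)
    X <- matrix(rnorm(4000 * n), ncol = n) %*% chol(S)
    rho <- partialCorrelation(solve(stats::cov(X)))
    i <- 1; j <- 2
    expect_equal(rho[i, j], residualPartialCor(X, i, j), tolerance = 1e-8)
  }
})

test_that("graphicalLasso at lambda = 0 is the inverse covariance", {
  S <- randomSpd(5, 42)
  expect_lt(max(abs(graphicalLasso(S, 0) - solve(S))), 1e-6)
})

test_that("graphicalLasso satisfies the full-sparsity KKT bound", {
  for (seed in 1:4) {
    S <- randomSpd(3, seed)
    lam <- max(abs(S[upper.tri(S)])) * 1.001
    theta <- graphicalLasso(S, lam)
    expect_equal(theta[upper.tri(theta)], numeric(3))
    # with the diagonal penalised the stationary diagonal is 1/(S_ii + lambda)
    expect_equal(diag(theta), 1 / (diag(S) + lam), tolerance = 1e-8)
  }
})

test_that("graphicalLasso matches an independent proximal-gradient solver", {
  for (seed in 1:6) {
    S <- randomSpd(4, seed + 20)
    lam <- c(0.05, 0.1, 0.2)[1 + seed %% 3]
    theta <- graphicalLasso(S, lam)
    objCd <- glassoObjective(theta, S, lam)
    oracle <- istaGlasso(S, lam)
    expect_lt(abs(objCd - oracle$objective), 1e-6)
    expect_lt(attr(theta, "gap"), 1e-6)
  }
})

test_that("penalty on the diagonal can be switched off", {
  S <- randomSpd(4, 7)
  lam <- 0.1
  thOff <- graphicalLasso(S, lam, penalizeDiagonal = FALSE)
  oracle <- istaGlasso(S, lam, penalizeDiagonal = FALSE)
  expect_lt(abs(glassoObjective(thOff, S, lam, FALSE) - oracle$objective), 1e-6)
  # excluding the diagonal from the penalty yields a larger (less shrunk) diagonal
  thOn <- graphicalLasso(S, lam, penalizeDiagonal = TRUE)
  expect_true(all(diag(thOff) >= diag(thOn) - 1e-10))
})

test_that("graphical-lasso sparsity is monotone non-increasing in lambda", {
  # the active set itself can transiently swap members along an L1 path, so
  # the robust invariant is cardinality: stronger penalties never yield
  # denser graphs
  for (seed in c(33, 44, 55, 66)) {
    S <- randomSpd(4, seed)
    grid <- c(0.01, 0.03, 0.08, 0.15, 0.3, 0.6)
    sizes <- vapply(grid, function(lam) {
      th <- graphicalLasso(S, lam)
      sum(abs(th[upper.tri(th)]) > 1e-10)
    }, numeric(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("selectLambda behaves on null data and respects refinements = 0", {
  set.seed(12)
  X <- matrix(rnorm(300 * 6), ncol = 6) # independent white envelopes
  lam0 <- selectLambda(X, refinements = 0L)
  grid <- exp(seq(log(1e-4), log(1), length.out = 16))
  expect_true(any(abs(as.numeric(lam0) - grid) < 1e-12))
  # under independence the choice should sit in the sparsest third of the grid
  expect_gte(as.numeric(lam0), grid[11])
})

test_that("selectLambda recovers the support of strongly networked envelopes", {
  hits <- 0
  nSeeds <- 5
  for (seed in seq_len(nSeeds)) {
    sim <- simulateExperiment(nNodes = 8, duration = 300, snr = 1,
                              seed = 400 + seed)
    bp <- bandpass(Timecourses(observedData(sim), samplingRate = 100),
                   c(4, 30))
    env <- downsampleEnvelope(hilbertEnvelope(symmetricOrthogonalise(bp)),
                              band = c(4, 30))
    lam <- as.numeric(selectLambda(values(env)))
    theta <- graphicalLasso(stats::cor(values(env)), lam)
    te <- matrix(FALSE, 8, 8)
    te[edgeList(groundTruth(sim))] <- TRUE
    te <- te | t(te)
    ut <- upper.tri(theta)
    if (all(abs(theta[ut & te]) > 1e-10)) hits <- hits + 1
  }
  expect_gte(hits, nSeeds - 1)
})

test_that("fisherZ is the antisymmetric arctanh with a guarded domain", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.95, 0.95, by = 0.19)
  expect_equal(fisherZ(-r), -fisherZ(r))
  expect_error(fisherZ(1), "< 1")
})

test_that("nullScaling grows with smoothness and shrinks with sample size", {
  sdSmooth <- nullScaling(6, 300, ar1 = 0.9, metric = "full", nNull = 30,
                          seed = 5)
  sdWhite <- nullScaling(6, 300, ar1 = 0.0, metric = "full", nNull = 30,
                         seed = 5)
  expect_gt(sdSmooth, sdWhite)
  sdLong <- nullScaling(6, 600, ar1 = 0.9, metric = "full", nNull = 30,
                        seed = 6)
  expect_lt(sdLong, sdSmooth)
  # scaling a fresh null draw by the returned sd restores unit spread
  fresh <- nullScaling(6, 300, ar1 = 0.9, metric = "full", nNull = 30,
                       seed = 99)
  expect_gt(fresh / sdSmooth, 0.9)
  expect_lt(fresh / sdSmooth, 1.1)
})

test_that("group fixed effects is the sqrt-S-scaled mean", {
  z1 <- matrix(0, 4, 4)
  cz0 <- new("CalibratedZ", z = z1, nullSd = 1, nSubjects = 1L)
  expect_equal(zMatrix(groupFixedEffects(list(cz0, cz0, cz0))), z1)

  set.seed(9)
  zm <- matrix(rnorm(16), 4); zm <- (zm + t(zm)) / 2; diag(zm) <- 0
  cz <- new("CalibratedZ", z = zm, nullSd = 1, nSubjects = 1L)
  g <- groupFixedEffects(list(cz, cz, cz, cz))
  expect_equal(zMatrix(g), zm * sqrt(4), tolerance = 1e-12)

  # S independent standard-normal subjects leave the edge scale unchanged
  set.seed(10)
  subj <- lapply(1:12, function(i) {
    m <- matrix(rnorm(100), 10); m <- (m + t(m)) / 2; diag(m) <- 0
    new("CalibratedZ", z = m, nullSd = 1, nSubjects = 1L)
  })
  gz <- zMatrix(groupFixedEffects(subj))
  pooled <- stats::sd(gz[upper.tri(gz)])
  expect_gt(pooled, 0.85 / sqrt(2)) # subject entries have sd 1/sqrt(2) after symmetrising
  expect_lt(pooled, 1.15 / sqrt(2))
})

test_that("the Benjamini-Hochberg step-up matches the by-hand worked example", {
  # p = {0.001, 0.02, 0.04, 0.8}, q = 0.05: thresholds i q/4 are
  # {0.0125, 0.025, 0.0375, 0.05}; the largest i with p(i) <= i q/4 is 2
  rej <- bhReject(c(0.001, 0.02, 0.04, 0.8), 0.05)
  expect_equal(sum(rej), 2)
  expect_equal(rej, c(TRUE, TRUE, FALSE, FALSE))
  expect_false(any(bhReject(rep(1, 6), 0.05)))
})

test_that("fdrThreshold masks edges and reports the implied z cut", {
  # all strongly positive: everything survives; threshold is the min z
  allGood <- matrix(10, 3, 3); diag(allGood) <- 0
  res <- fdrThreshold(allGood)
  expect_equal(sum(res$mask) / 2, 3)
  expect_equal(res$threshold, 10)

  # all null: nothing survives
  allBad <- matrix(-10, 3, 3); diag(allBad) <- 0
  expect_equal(sum(fdrThreshold(allBad)$mask), 0)
  expect_equal(fdrThreshold(allBad)$threshold, Inf)

  # mixed case: mask is symmetric and only the strong edge survives
  zm <- matrix(0, 4, 4)
  zm[1, 2] <- zm[2, 1] <- 6
  res <- fdrThreshold(zm, q = 0.05)
  expect_true(res$mask[1, 2] && res$mask[2, 1])
  expect_equal(sum(res$mask) / 2, 1)
  expect_error(fdrThreshold(zm, q = 1.2), "0, 1")
})
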