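test_that("sampleNetwork builds the system matrix the dynamics expect", {
  empty <- sampleNetwork(4, matrix(integer(0), 0, 2), seed = 1)
  expect_equal(systemMatrix(empty), diag(-1, 4))

  truth <- sampleNetwork(5, defaultNetworkEdges(), seed = 2)
  A <- systemMatrix(truth)
  expect_equal(diag(A), rep(-1, 5))
  expect_equal(sum(A != 0 & row(A) != col(A)), 6) # the 6-edge example layout

  # sampled weights follow N(0.6, 0.1)
  w <- vapply(1:1000, function(s)
    systemMatrix(sampleNetwork(2, matrix(c(1L, 2L), 1), seed = s))[2, 1],
    numeric(1))
  expect_lt(abs(mean(w) - 0.6), 0.02)
  expect_lt(abs(stats::sd(w) - 0.1), 0.02)

  expect_error(sampleNetwork(3, cbind(1L, 1L)), "self-edges")
})

test_that("poissonDrive is an alternating renewal process with the stated means", {
  dr <- poissonDrive(10000, dt = 0.02, nNodes = 1, seed = 4)
  u <- dr@u[, 1]
  expect_true(all(u %in% c(0, 0.4)))
  # renewal-reward: long-run mean = strength * meanOn / (meanOn + meanOff)
  expect_lt(abs(mean(u) - 0.4 * 2 / 9) / (0.4 * 2 / 9), 0.1)
  # mean on-run duration ~ 2 s
  r <- rle(u > 0)
  onLens <- r$lengths[r$values] * 0.02
  expect_lt(abs(mean(onLens) - 2) / 2, 0.1)

  expect_error(poissonDrive(10, dt = 0.5), "meanOn/10")
})

test_that("integrateActivity reproduces closed-form linear dynamics", {
  # pure decay from a(0) = 1: a(t) = exp(-t)
  truth <- sampleNetwork(1, matrix(integer(0), 0, 2), seed = 1)
  m <- 200; dt <- 0.01
  quiet <- new("DriveProcess", u = matrix(0, m, 1), strength = 0,
               meanOn = 2, meanOff = 7, dt = dt)
  a <- integrateActivity(truth, quiet, noiseVar = 0, a0 = 1)
  expect_lt(max(abs(a[, 1] - exp(-dt * seq_len(m)))), 1e-6)

  # constant drive u = 0.4: fixed point -A^{-1} u = 0.4
  drive <- new("DriveProcess", u = matrix(0.4, 1000, 1), strength = 0.4,
               meanOn = 2, meanOff = 7, dt = dt)
  a <- integrateActivity(truth, drive, noiseVar = 0)
  expect_lt(abs(a[1000, 1] - 0.4), 1e-4)

  expect_error(integrateActivity(truth,
    new("DriveProcess", u = matrix(0, 10, 1), strength = 0, meanOn = 2,
        meanOff = 7, dt = 0.5), noiseVar = 0), "too coarse")
})

test_that("a directed edge induces stronger activity correlation than chance", {
  edges <- cbind(1L, 2L)
  truth <- sampleNetwork(4, edges, seed = 6)
  dr <- poissonDrive(600, dt = 0.01, nNodes = 4, seed = 7)
  a <- integrateActivity(truth, dr, seed = 8)
  C <- stats::cor(a)
  connected <- C[1, 2]
  unconnected <- c(C[1, 3], C[1, 4], C[2, 3], C[2, 4], C[3, 4])
  expect_gt(connected, max(unconnected))
})

test_that("modulate places spectral power at the assigned carriers", {
  expect_equal(modulate(matrix(0, 100, 2), c(10, 15), samplingRate = 100),
               matrix(0, 100, 2))

  fs <- 100
  tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
  act <- cbind(1 + 0.3 * sin(2 * pi * 0.1 * tt),
               1 + 0.3 * cos(2 * pi * 0.2 * tt))
  src <- modulate(act, c(10, 21), samplingRate = fs, seed = 2)
  for (j in 1:2) {
    sp <- stats::spec.pgram(src[, j], plot = FALSE, taper = 0)
    peak <- sp$freq[which.max(sp$spec)] * fs
    expect_lt(abs(peak - c(10, 21)[j]), 0.5)
  }
  # the Hilbert envelope of a modulated carrier recovers |a|
  env <- values(hilbertEnvelope(Timecourses(src, samplingRate = fs)))
  interior <- seq(fs, length(tt) - fs)
  expect_gt(stats::cor(env[interior, 1], abs(act[interior, 1])), 0.9)

  expect_error(modulate(act, c(10, 10), samplingRate = fs), "distinct")
  expect_error(modulate(act, c(10, 60), samplingRate = fs), "Nyquist")
})

test_that("leakageMix induces zero-lag neighbour correlation at the stated SNR", {
  set.seed(3)
  src <- matrix(rnorm(6000 * 4), ncol = 4)

  # identity corner
  clean <- leakageMix(src, spread = 0, noiseSnr = Inf)
  expect_equal(clean$observed, src)
  expect_equal(clean$mixing, diag(4))

  mixed <- leakageMix(src, spread = 1, noiseSnr = 1, seed = 5)
  expect_equal(rowSums(mixed$mixing), rep(1, 4))
  # white independent sources: neighbouring observed nodes peak at lag 0
  cc <- stats::ccf(mixed$observed[, 2], mixed$observed[, 3], lag.max = 20,
                   plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # realised SNR within 1% of target
  noise <- mixed$observed - src %*% t(mixed$mixing)
  snrHat <- mean((src %*% t(mixed$mixing))^2) / stats::var(as.vector(noise))
  expect_lt(abs(snrHat - 1), 0.01 + 3 * sqrt(2 / length(noise)))

  expect_error(leakageMix(src, spread = 1, noiseSnr = 0), "positive")
})

test_that("ar1Null draws independent unit-variance AR(1) columns", {
  m <- 10000
  white <- values(ar1Null(4, m, phi = 0, seed = 9))
  lag1 <- apply(white, 2, function(x) stats::cor(x[-1], x[-m]))
  expect_true(all(abs(lag1) < 3 / sqrt(m)))

  sm <- values(ar1Null(4, m, phi = 0.8, seed = 10))
  lag1 <- apply(sm, 2, function(x) stats::cor(x[-1], x[-m]))
  expect_true(all(abs(lag1 - 0.8) < 0.05))
  expect_true(all(abs(apply(sm, 2, stats::sd) - 1) < 0.1))

  C <- stats::cor(sm)
  expect_lt(max(abs(C[upper.tri(C)])), 3.5 / sqrt(m))
  expect_error(ar1Null(2, 100, phi = 1), "phi")
})

test_that("identical seeds give bit-identical simulation bundles", {
  s1 <- simulateExperiment(nNodes = 6, duration = 30, seed = 17)
  s2 <- simulateExperiment(nNodes = 6, duration = 30, seed = 17)
  expect_identical(observedData(s1), observedData(s2))
  expect_identical(sourceData(s1), sourceData(s2))
  expect_identical(systemMatrix(groundTruth(s1)), systemMatrix(groundTruth(s2)))
  s3 <- simulateExperiment(nNodes = 6, duration = 30, seed = 18)
  expect_false(identical(observedData(s1), observedData(s3)))
})
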