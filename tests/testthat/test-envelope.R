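fs <- 200
t10 <- seq(0, 30 - 1 / fs, by = 1 / fs)

test_that("bandpass passes in-band and suppresses out-of-band sinusoids", {
  inband <- sin(2 * pi * 10 * t10)
  outband <- sin(2 * pi * 40 * t10)
  tc <- Timecourses(cbind(inband, outband, 0), samplingRate = fs)
  out <- values(bandpass(tc, c(8, 13)))
  interior <- seq(2 * fs, length(t10) - 2 * fs)
  # in-band amplitude preserved within 5%
  expect_lt(abs(max(out[interior, 1]) - 1), 0.05)
  # out-of-band RMS crushed below 5%
  expect_lt(sqrt(mean(out[interior, 2]^2)) / sqrt(0.5), 0.05)
  # zero in, zero out
  expect_equal(max(abs(out[, 3])), 0)
})

test_that("bandpass filtering is zero-phase", {
  pulse <- exp(-(t10 - 15)^2 / 0.5) * cos(2 * pi * 10 * (t10 - 15))
  out <- values(bandpass(Timecourses(cbind(pulse), samplingRate = fs),
                         c(8, 13)))[, 1]
  # a pulse symmetric about t = 15 s stays symmetric about t = 15 s
  centre <- which.min(abs(t10 - 15))
  w <- 2 * fs
  expect_lt(max(abs(out[(centre - w):(centre + w)] -
                    rev(out[(centre - w):(centre + w)]))),
            1e-6 * max(abs(out)))
})

test_that("bandpass validates the band against Nyquist", {
  tc <- Timecourses(matrix(rnorm(400), 200, 2), samplingRate = fs)
  expect_error(bandpass(tc, c(0, 10)), "Nyquist")
  expect_error(bandpass(tc, c(90, 110)), "Nyquist")
  expect_error(bandpass(tc, c(13, 8)), "Nyquist")
})

test_that("hilbertEnvelope recovers amplitudes of band-limited oscillations", {
  # constant-amplitude tone: envelope flat at A away from the edges
  A <- 2.5
  x <- A * sin(2 * pi * 10 * t10)
  env <- values(hilbertEnvelope(Timecourses(cbind(x), samplingRate = fs)))[, 1]
  interior <- seq(fs, length(t10) - fs)
  expect_lt(max(abs(env[interior] - A)) / A, 0.02)

  # zero in, zero out
  z <- values(hilbertEnvelope(Timecourses(matrix(0, 64, 1), samplingRate = fs)))
  expect_equal(max(abs(z)), 0)

  # slow nonnegative modulation is tracked almost perfectly
  a <- 1.5 + sin(2 * pi * 0.2 * t10)
  env <- values(hilbertEnvelope(
    Timecourses(cbind(a * sin(2 * pi * 15 * t10)), samplingRate = fs)))[, 1]
  expect_gt(stats::cor(env[interior], a[interior]), 0.99)

  expect_error(hilbertEnvelope(Timecourses(matrix(1, 8, 1), samplingRate = fs)),
               "16 samples")
})

test_that("envelope sample counts follow from duration, rates and trim", {
  dur <- 600
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  env <- Timecourses(matrix(abs(rnorm(length(tt) * 2)), ncol = 2),
                     samplingRate = fs)
  out <- downsampleEnvelope(env, lowpass = 0.5, outRate = 1, trim = 1)
  expect_equal(nrow(values(out)), dur - 2L) # 600 s -> 598 one-second samples
  expect_equal(envelopeRate(out), 1)
})

test_that("downsampleEnvelope preserves slow and removes fast modulation", {
  cst <- Timecourses(matrix(3.2, length(t10), 1), samplingRate = fs)
  out <- values(downsampleEnvelope(cst))[, 1]
  expect_lt(max(abs(out - 3.2)), 1e-6)

  slow <- 2 + sin(2 * pi * 0.1 * t10)
  fast <- 2 + sin(2 * pi * 2 * t10)
  env <- Timecourses(cbind(slow, fast), samplingRate = fs)
  out <- values(downsampleEnvelope(env))
  kept <- seq(1, 28, by = 1) # decimated truth at the output instants
  truthSlow <- 2 + sin(2 * pi * 0.1 * kept)
  expect_gt(stats::cor(out[, 1], truthSlow), 0.95)
  # 2 Hz modulation is far beyond the 0.5 Hz cutoff: amplitude crushed
  expect_lt(stats::sd(out[, 2]), 0.05 * stats::sd(fast))
})

test_that("downsampleEnvelope validates its rates", {
  env <- Timecourses(matrix(1, 100, 1), samplingRate = 0.8)
  expect_error(downsampleEnvelope(env, lowpass = 0.5), "exceed")
  env2 <- Timecourses(matrix(1, 1000, 1), samplingRate = 100)
  expect_error(downsampleEnvelope(env2, lowpass = 0.5, outRate = 0.5),
               "at least twice")
})

test_that("roiTimecourse extracts the dominant weighted component", {
  set.seed(4)
  m <- 400
  # single voxel: returned series correlates perfectly with it
  v <- matrix(rnorm(m), ncol = 1)
  expect_equal(abs(stats::cor(roiTimecourse(v, 1), v[, 1])), 1,
               tolerance = 1e-10)

  # identical voxels: ditto
  v2 <- cbind(v, v)
  expect_equal(abs(stats::cor(roiTimecourse(v2, c(1, 1)), v[, 1])), 1,
               tolerance = 1e-10)

  # shared signal + independent noise: the component beats every voxel
  shared <- rnorm(m)
  vox <- sapply(1:10, function(i) shared + rnorm(m, sd = 1.5))
  w <- runif(10, 0.5, 2)
  pc <- roiTimecourse(vox, w)
  corPc <- abs(stats::cor(pc, shared))
  corVox <- apply(vox, 2L, function(x) abs(stats::cor(x, shared)))
  expect_gt(corPc, max(corVox))

  # the sign convention follows the weighted mean
  expect_gte(stats::cor(pc, rowMeans(sweep(vox, 2, w / max(w), `*`))), 0)
})

test_that("roiTimecourse explained variance equals the leading eigenvalue fraction", {
  set.seed(5)
  vox <- matrix(rnorm(200 * 6), 200, 6) %*% diag(runif(6, 0.5, 2))
  w <- runif(6, 0.1, 1)
  pc <- roiTimecourse(vox, w)
  X <- sweep(vox, 2L, w / max(w), `*`)
  ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(attr(pc, "explainedVariance"), ev[1] / sum(ev),
               tolerance = 1e-8)
})

test_that("roiTimecourse rejects degenerate inputs", {
  expect_error(roiTimecourse(matrix(0, 10, 2), c(1, 1)), "degenerate")
  expect_error(roiTimecourse(matrix(rnorm(20), 10, 2), c(0, 0)), "weights")
})
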