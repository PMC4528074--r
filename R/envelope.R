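# Steady-state initial filter state for a step of unit height (the
# lfilter_zi construction): solving (I - companion(a)') zi = b[-1] - a[-1] b[1]
# makes the filter start in equilibrium, so edges produce no step transient.
.lfilterZi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  comp <- rbind(-a[-1] / a[1],
                cbind(diag(1, n - 2), numeric(n - 2)))
  solve(diag(n - 1) - t(comp), b[-1] - a[-1] * b[1])
}

# Zero-phase IIR filtering: odd-reflection padding at both ends plus
# steady-state initialisation, then one forward and one reverse pass.
.filtfilt <- function(filt, x) {
  b <- filt$b
  a <- filt$a
  nfact <- 3L * (max(length(a), length(b)) - 1L)
  m <- length(x)
  if (m <= nfact + 1L)
    stop(sprintf("need more than %d samples for this filter", nfact + 1L))
  xx <- c(2 * x[1] - x[(nfact + 1L):2],
          x,
          2 * x[m] - x[(m - 1L):(m - nfact)])
  zi <- .lfilterZi(b, a)
  y <- lfilter_cpp(b, a, xx, zi * xx[1])
  y <- rev(lfilter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[(nfact + 1L):(nfact + m)]
}

#' Zero-phase band-pass filter
#'
#' Filters every node time-course with a 4th-order Butterworth band-pass
#' applied forward and backward (with odd-reflection padding and
#' steady-state initialisation at the ends), so the output has zero phase
#' distortion and no edge step transients. Zero-phase filtering matters here: the leakage
#' correction removes *zero-lag* correlations, and a causal filter would
#' smear the mixing structure across lags.
#'
#' @param ts a [Timecourses-class] object.
#' @param band numeric `c(low, high)` in Hz; must satisfy
#'   `0 < low < high < samplingRate / 2`.
#' @param order Butterworth order per pass (default 4).
#' @return a band-limited [Timecourses-class] object.
#' @export
bandpass <- function(ts, band, order = 4L) {
  stopifnot(is(ts, "Timecourses"))
  fs <- ts@samplingRate
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2] ||
      band[2] >= fs / 2)
    stop(sprintf("band must satisfy 0 < low < high < Nyquist (%g Hz)", fs / 2))
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  out <- apply(ts@values, 2L, function(x) .filtfilt(bf, x))
  Timecourses(out, samplingRate = fs, nodeLabels = ts@nodeLabels)
}

#' Hilbert amplitude envelope
#'
#' Per-column magnitude of the analytic signal: the signal plus i times its
#' Hilbert transform, computed by one-sided spectrum doubling in the
#' frequency domain. For a band-limited oscillation `a(t) sin(2 pi f t)` with
#' slowly varying nonnegative amplitude the result tracks `a(t)`.
#'
#' @param ts a [Timecourses-class] object (>= 16 samples).
#' @return a [Timecourses-class] object of nonnegative envelopes at the same
#'   sampling rate.
#' @export
hilbertEnvelope <- function(ts) {
  stopifnot(is(ts, "Timecourses"))
  m <- nrow(ts@values)
  if (m < 16L) stop("need at least 16 samples for a usable analytic signal")
  h <- numeric(m)
  if (m %% 2 == 0) {
    h[c(1L, m / 2 + 1L)] <- 1
    h[2:(m / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((m + 1) / 2)] <- 2
  }
  X <- stats::mvfft(ts@values) * h
  env <- abs(stats::mvfft(X, inverse = TRUE)) / m
  Timecourses(env, samplingRate = ts@samplingRate, nodeLabels = ts@nodeLabels)
}

#' Low-pass filter and downsample an envelope
#'
#' Completes the power-envelope pipeline: the raw-rate Hilbert envelope is
#' low-pass filtered (zero-phase Butterworth, default cutoff 0.5 Hz), a
#' fixed edge segment is trimmed from each end to discard analytic-transform
#' and filter transients, and the result is resampled at `outRate`
#' (default 1 Hz) by decimation (linear interpolation when the rate ratio is
#' not an integer).
#'
#' @param env a [Timecourses-class] object holding raw-rate envelopes.
#' @param lowpass low-pass cutoff in Hz (default 0.5); requires
#'   `samplingRate > 2 * lowpass`.
#' @param outRate output envelope rate in Hz (default 1); requires
#'   `outRate >= 2 * lowpass`.
#' @param trim seconds discarded from each end before resampling (default 1).
#' @param band the carrier band the envelopes came from, recorded as
#'   metadata.
#' @param order Butterworth order per pass (default 4).
#' @return an [EnvelopeMatrix-class] with
#'   `floor((duration - 2 * trim) * outRate) + 1` rows.
#' @export
downsampleEnvelope <- function(env, lowpass = 0.5, outRate = 1, trim = 1,
                               band = c(NA_real_, NA_real_), order = 4L) {
  stopifnot(is(env, "Timecourses"))
  fs <- env@samplingRate
  if (fs <= 2 * lowpass)
    stop(sprintf("envelope rate %g Hz must exceed twice the low-pass cutoff %g Hz",
                 fs, lowpass))
  if (outRate < 2 * lowpass)
    stop(sprintf("output rate %g Hz must be at least twice the low-pass cutoff %g Hz",
                 outRate, lowpass))
  bf <- signal::butter(order, lowpass / (fs / 2), type = "low")
  sm <- apply(env@values, 2L, function(x) .filtfilt(bf, x))
  m <- nrow(sm)
  tEnd <- (m - 1) / fs
  keep <- seq(trim, tEnd - trim, by = 1 / outRate)
  if (length(keep) < 2L) stop("too few samples left after edge trimming")
  tIn <- (seq_len(m) - 1) / fs
  out <- apply(sm, 2L, function(x) stats::approx(tIn, x, xout = keep)$y)
  if (all(is.na(band))) band <- c(0, fs / 2)
  new("EnvelopeMatrix", values = out, envelopeRate = as.numeric(outRate),
      sourceBand = as.numeric(band), nodeLabels = env@nodeLabels)
}

#' Band-limited power envelopes in one call
#'
#' Convenience composition of [bandpass()], [hilbertEnvelope()] and
#' [downsampleEnvelope()] — the full pipeline from raw node time-courses to
#' the low-rate power envelopes that the network estimators consume.
#'
#' @inheritParams bandpass
#' @inheritParams downsampleEnvelope
#' @return an [EnvelopeMatrix-class].
#' @examples
#' tc <- Timecourses(matrix(rnorm(3000 * 3), ncol = 3), samplingRate = 100)
#' powerEnvelope(tc, band = c(8, 13))
#' @export
powerEnvelope <- function(ts, band, lowpass = 0.5, outRate = 1, trim = 1,
                          order = 4L) {
  env <- hilbertEnvelope(bandpass(ts, band, order = order))
  downsampleEnvelope(env, lowpass = lowpass, outRate = outRate, trim = trim,
                     band = band, order = order)
}

#' Collapse a multi-voxel region to one representative time-course
#'
#' Scales each voxel series by its (nonnegative) spatial-map weight — the
#' weight map is first normalised to a positive peak of one — then returns
#' the scores of the first principal component of the weighted voxel set.
#' The sign is fixed so the result correlates nonnegatively with the
#' weighted mean time-course.
#'
#' @param voxels numeric matrix, samples x voxels.
#' @param weights nonnegative spatial-map weights, one per voxel, not all
#'   zero.
#' @return a numeric vector of length `nrow(voxels)` together with
#'   attribute `"explainedVariance"`, the leading eigenvalue fraction.
#' @export
roiTimecourse <- function(voxels, weights) {
  voxels <- as.matrix(voxels)
  weights <- as.numeric(weights)
  if (length(weights) != ncol(voxels))
    stop("need one weight per voxel column")
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be nonnegative and not all zero")
  if (all(voxels == 0)) stop("degenerate input: all voxel data are zero")
  weights <- weights / max(weights)
  X <- sweep(voxels, 2L, weights, `*`)
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc, nu = 1L, nv = 0L)
  pc <- sv$u[, 1L] * sv$d[1L]
  wm <- rowMeans(X)
  if (sum(pc * (wm - mean(wm))) < 0) pc <- -pc
  attr(pc, "explainedVariance") <- sv$d[1L]^2 / sum(sv$d^2)
  pc
}
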