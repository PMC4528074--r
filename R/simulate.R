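#' Built-in example network layout
#'
#' A canonical directed 5-node, 6-edge layout used as the package's example
#' ground-truth network: a connected graph with one feed-forward chain, a
#' shortcut and a feedback edge, giving every node at least one connection.
#'
#' @return integer matrix, 6 x 2, rows are directed `(from, to)` edges among
#'   nodes 1..5.
#' @export
defaultNetworkEdges <- function() {
  cbind(from = c(1L, 2L, 1L, 4L, 3L, 5L),
        to   = c(2L, 3L, 4L, 5L, 5L, 2L))
}

#' Sample a ground-truth network system matrix
#'
#' Builds the system matrix `A` of the linear stochastic network model:
#' diagonal entries -1 (within-node temporal decay, time constant 1 s) and,
#' at each requested directed edge, a coupling strength drawn from
#' `N(strengthMean, strengthSd^2)` (defaults 0.6 and 0.1).
#'
#' @param nNodes number of nodes.
#' @param edges integer matrix, k x 2, directed `(from, to)` pairs;
#'   self-edges are rejected.
#' @param strengthMean,strengthSd edge-weight distribution parameters.
#' @param seed integer seed.
#' @return a [NetworkGroundTruth-class].
#' @examples
#' sampleNetwork(5, defaultNetworkEdges(), seed = 1)
#' @export
sampleNetwork <- function(nNodes, edges, strengthMean = 0.6,
                          strengthSd = 0.1, seed = 1L) {
  edges <- matrix(as.integer(edges), ncol = 2L,
                  dimnames = list(NULL, c("from", "to")))
  if (nrow(edges) > 0 && any(edges[, 1] == edges[, 2]))
    stop("self-edges are not allowed")
  if (nrow(edges) > 0 && (max(edges) > nNodes || min(edges) < 1L))
    stop("edge indices must lie in 1..nNodes")
  set.seed(seed)
  A <- diag(-1, nNodes)
  if (nrow(edges) > 0) {
    w <- rnorm(nrow(edges), strengthMean, strengthSd)
    A[edges[, c(2L, 1L), drop = FALSE]] <- w # A[to, from]: input from -> to
  }
  new("NetworkGroundTruth", A = A, edges = edges,
      strengthMean = strengthMean, strengthSd = strengthSd)
}

#' Binary Poisson burst drive
#'
#' Generates, independently for each node, an alternating-renewal on/off
#' process with exponentially distributed on and off durations (means
#' `meanOn` and `meanOff` seconds), taking the value `strength` while on and
#' 0 while off. The initial state is drawn from the stationary distribution,
#' with on-probability `meanOn / (meanOn + meanOff)`.
#'
#' @param duration total length in seconds.
#' @param dt time step in seconds; must satisfy `dt < meanOn / 10`.
#' @param nNodes number of independent drive processes.
#' @param strength drive amplitude while on (default 0.4).
#' @param meanOn,meanOff mean on/off durations in seconds (defaults 2 and 7).
#' @param seed integer seed.
#' @return a [DriveProcess-class] with `round(duration / dt)` rows.
#' @export
poissonDrive <- function(duration, dt, nNodes = 1L, strength = 0.4,
                         meanOn = 2, meanOff = 7, seed = 1L) {
  if (dt >= meanOn / 10)
    stop(sprintf("dt = %g must be below meanOn/10 = %g to resolve the bursts",
                 dt, meanOn / 10))
  set.seed(seed)
  m <- round(duration / dt)
  u <- matrix(0, m, nNodes)
  pOn <- meanOn / (meanOn + meanOff)
  for (j in seq_len(nNodes)) {
    on <- runif(1) < pOn
    pos <- 0L
    while (pos < m) {
      len <- max(1L, round(rexp(1, 1 / if (on) meanOn else meanOff) / dt))
      if (on) u[(pos + 1L):min(m, pos + len), j] <- strength
      pos <- pos + len
      on <- !on
    }
  }
  new("DriveProcess", u = u, strength = strength, meanOn = meanOn,
      meanOff = meanOff, dt = dt)
}

#' Integrate the network activity model
#'
#' Integrates the linear stochastic network dynamics
#' `da/dt = A a + u + e` with a fourth-order Runge-Kutta scheme at the drive
#' time step, starting from `a(0) = 0`. The Gaussian input `e` (variance
#' `noiseVar` per node) is redrawn every step and held constant within it:
#' the model is treated as the printed ordinary differential equation with a
#' noisy forcing term, not as a formal stochastic differential equation, so
#' no `1/sqrt(dt)` increment scaling is applied. Because `A` and the step
#' are fixed, the RK4 update reduces to the exact one-step polynomial maps
#' `M = sum_{i=0..4} (dt A)^i / i!` and
#' `N = dt sum_{i=0..3} (dt A)^i / (i+1)!`, applied as
#' `a[k+1] = M a[k] + N (u[k] + e[k])`.
#'
#' @param truth a [NetworkGroundTruth-class].
#' @param drive a [DriveProcess-class] with one column per node.
#' @param noiseVar variance of the Gaussian input per node (default 0.02).
#' @param a0 initial state (default all zero).
#' @param seed integer seed for the noise input.
#' @return samples x nodes matrix of activities, at the drive's time step.
#' @export
integrateActivity <- function(truth, drive, noiseVar = 0.02, a0 = NULL,
                              seed = 1L) {
  A <- truth@A
  n <- ncol(A)
  if (ncol(drive@u) != n)
    stop("drive must have one column per network node")
  dt <- drive@dt
  if (dt > 0.1)
    stop(sprintf("dt = %g is too coarse for stable integration (need <= 0.1)", dt))
  hA <- dt * A
  M <- diag(n)
  N <- dt * diag(n)
  term <- diag(n)
  for (i in 1:4) {
    term <- term %*% hA / i
    M <- M + term
    if (i < 4) N <- N + dt * term / (i + 1)
  }
  set.seed(seed)
  m <- nrow(drive@u)
  E <- matrix(rnorm(m * n, sd = sqrt(noiseVar)), m, n)
  a <- matrix(0, m, n)
  state <- if (is.null(a0)) numeric(n) else as.numeric(a0)
  if (length(state) != n) stop("'a0' must have one entry per node")
  for (k in seq_len(m)) {
    state <- M %*% state + N %*% (drive@u[k, ] + E[k, ])
    if (!all(is.finite(state)))
      stop(sprintf("integration became non-finite at step %d (dt = %g)", k, dt))
    a[k, ] <- state
  }
  a
}

#' Modulate carrier oscillators by node activities
#'
#' Produces each node's source signal `a_j(t) sin(2 pi f_j t + phi_j)` with a
#' random initial phase per node. Activities sampled at a different rate are
#' resampled to `samplingRate` by linear interpolation.
#'
#' @param activities samples x nodes matrix of amplitudes.
#' @param carriers one distinct carrier frequency (Hz) per node, below the
#'   Nyquist rate; `NULL` assigns frequencies evenly spaced in 8-26 Hz.
#' @param samplingRate output rate in Hz.
#' @param activityRate rate the activities were integrated at (defaults to
#'   `samplingRate`).
#' @param seed integer seed for the initial phases.
#' @return samples x nodes matrix of modulated sources.
#' @export
modulate <- function(activities, carriers = NULL, samplingRate,
                     activityRate = samplingRate, seed = 1L) {
  activities <- as.matrix(activities)
  n <- ncol(activities)
  if (is.null(carriers)) carriers <- seq(8, 26, length.out = max(n, 2L))[seq_len(n)]
  if (length(carriers) != n) stop("need one carrier per node")
  if (anyDuplicated(carriers)) stop("carrier frequencies must be distinct")
  if (any(carriers >= samplingRate / 2))
    stop("carriers must lie below the Nyquist frequency")
  if (activityRate != samplingRate) {
    tIn <- (seq_len(nrow(activities)) - 1) / activityRate
    tOut <- seq(0, tIn[length(tIn)], by = 1 / samplingRate)
    activities <- apply(activities, 2L, function(x)
      stats::approx(tIn, x, xout = tOut)$y)
  }
  set.seed(seed)
  phases <- runif(n, 0, 2 * pi)
  t <- (seq_len(nrow(activities)) - 1) / samplingRate
  carrierWave <- sin(outer(t, 2 * pi * carriers) +
                     matrix(phases, nrow(activities), n, byrow = TRUE))
  activities * carrierWave
}

#' Zero-lag leakage mixing with observation noise
#'
#' Emulates the zero-phase-lag cross-contamination ("leakage") that
#' ill-posed source reconstruction induces, as an explicit linear mixing
#' operator: nodes sit on a 1-D coordinate (default 1..n), and row `i` of
#' the mixing matrix is a Gaussian profile
#' `exp(-distance(i, j)^2 / (2 spread^2))`, row-normalised to sum to one.
#' `spread = 0` gives identity mixing. White Gaussian noise is then added,
#' scaled so that the mean-square mixed signal divided by the noise variance
#' equals `noiseSnr` (`Inf` for noise-free).
#'
#' @param sources samples x nodes matrix of source signals.
#' @param spread Gaussian mixing width in coordinate units (>= 0).
#' @param noiseSnr target signal-to-noise power ratio (> 0, may be `Inf`).
#' @param coords optional node coordinates (default `1:n`).
#' @param seed integer seed for the noise.
#' @return list with `observed` (samples x nodes) and `mixing` (n x n).
#' @export
leakageMix <- function(sources, spread, noiseSnr, coords = NULL, seed = 1L) {
  sources <- as.matrix(sources)
  n <- ncol(sources)
  if (spread < 0) stop("'spread' must be nonnegative")
  if (noiseSnr <= 0) stop("'noiseSnr' must be positive (use Inf for noise-free)")
  if (is.null(coords)) coords <- seq_len(n)
  if (length(coords) != n) stop("need one coordinate per node")
  if (spread == 0) {
    mixing <- diag(n)
  } else {
    D2 <- outer(coords, coords, function(a, b) (a - b)^2)
    mixing <- exp(-D2 / (2 * spread^2))
    mixing <- mixing / rowSums(mixing)
  }
  observed <- sources %*% t(mixing)
  noiseSd <- 0
  if (is.finite(noiseSnr)) {
    noiseSd <- sqrt(mean(observed^2) / noiseSnr)
    set.seed(seed)
    observed <- observed + matrix(rnorm(length(observed), sd = noiseSd),
                                  nrow(observed), n)
  }
  list(observed = observed, mixing = mixing, noiseSd = noiseSd)
}

#' Independent AR(1) null time-courses
#'
#' Stationary first-order autoregressive columns with unit marginal
#' variance, `x_t = phi x_(t-1) + sqrt(1 - phi^2) eps_t`, mutually
#' independent across nodes — the surrogate null data used for
#' empirical-null calibration.
#'
#' @param nNodes,nSamples matrix dimensions.
#' @param phi lag-1 autocorrelation, `|phi| < 1`.
#' @param seed integer seed.
#' @param samplingRate rate recorded on the returned object (default 1).
#' @return a [Timecourses-class] object.
#' @export
ar1Null <- function(nNodes, nSamples, phi, seed = 1L, samplingRate = 1) {
  if (abs(phi) >= 1) stop("'phi' must satisfy |phi| < 1")
  set.seed(seed)
  X <- matrix(rnorm(nSamples * nNodes), nSamples, nNodes)
  if (phi != 0) {
    innovSd <- sqrt(1 - phi^2)
    X[-1L, ] <- X[-1L, ] * innovSd
    for (k in 2:nSamples) X[k, ] <- phi * X[k - 1L, ] + X[k, ]
  }
  Timecourses(X, samplingRate = samplingRate)
}

#' Simulate one full experiment
#'
#' Generates a complete synthetic recording: a ground-truth network over the
#' first `length(networkedNodes)` nodes (the rest receive identical but
#' uncorrelated dynamics with no network structure), Poisson-burst-driven
#' linear network activities, carrier modulation, zero-lag leakage mixing
#' and additive observation noise. Identical seeds give bit-identical
#' bundles.
#'
#' @param nNodes total number of nodes (default 38).
#' @param edges directed edges among the networked nodes, as row indices
#'   into `networkedNodes` (default [defaultNetworkEdges()]).
#' @param networkedNodes which node positions carry the networked dynamics
#'   (default the first five).
#' @param duration seconds of data (default 600).
#' @param samplingRate acquisition rate in Hz (default 100).
#' @param snr signal-to-noise power ratio of the observations (default 1).
#' @param spread leakage mixing width (default 0.6 node spacings).
#' @param strengthMean,strengthSd edge-weight distribution (defaults 0.6,
#'   0.1).
#' @param driveStrength,meanOn,meanOff burst-drive parameters (defaults 0.4,
#'   2 s, 7 s).
#' @param noiseVar activity input-noise variance (default 0.02).
#' @param carriers carrier frequencies; `NULL` spaces them evenly in
#'   8-26 Hz.
#' @param seed integer seed governing every random draw.
#' @return a [SimulationBundle-class].
#' @examples
#' sim <- simulateExperiment(nNodes = 8, duration = 60, seed = 1)
#' sim
#' @export
simulateExperiment <- function(nNodes = 38L, edges = defaultNetworkEdges(),
                               networkedNodes = seq_len(5L),
                               duration = 600, samplingRate = 100,
                               snr = 1, spread = 0.6,
                               strengthMean = 0.6, strengthSd = 0.1,
                               driveStrength = 0.4, meanOn = 2, meanOff = 7,
                               noiseVar = 0.02, carriers = NULL, seed = 1L) {
  seed <- as.integer(seed)
  if (max(networkedNodes) > nNodes)
    stop("'networkedNodes' must index into 1..nNodes")
  edgesGlobal <- cbind(from = networkedNodes[edges[, 1]],
                       to = networkedNodes[edges[, 2]])
  truth <- sampleNetwork(nNodes, edgesGlobal, strengthMean, strengthSd,
                         seed = seed)
  dt <- 1 / samplingRate
  drive <- poissonDrive(duration, dt, nNodes = nNodes,
                        strength = driveStrength, meanOn = meanOn,
                        meanOff = meanOff, seed = seed + 1L)
  activities <- integrateActivity(truth, drive, noiseVar = noiseVar,
                                  seed = seed + 2L)
  sources <- modulate(activities, carriers = carriers,
                      samplingRate = samplingRate, seed = seed + 3L)
  mixed <- leakageMix(sources, spread = spread, noiseSnr = snr,
                      seed = seed + 4L)
  if (is.null(carriers))
    carriers <- seq(8, 26, length.out = max(nNodes, 2L))[seq_len(nNodes)]
  new("SimulationBundle", truth = truth, activities = activities,
      sources = sources, observed = mixed$observed, mixing = mixed$mixing,
      carriers = as.numeric(carriers), noiseSd = mixed$noiseSd,
      snr = snr, samplingRate = samplingRate, seed = seed)
}
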