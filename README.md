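# leakmend

Symmetric leakage correction and envelope connectomes for multichannel
oscillatory signals.

## What problem this solves

Reconstructing many source signals from a common set of indirect
measurements (the textbook case: cortical region-of-interest time-courses
beamformed from MEG sensors) couples the reconstructions over space. This
"source leakage" is linear and instantaneous, so it manufactures
correlations between nearby signals **at zero lag** — and any amplitude- or
envelope-correlation network built on such signals is contaminated by
spurious local edges. Existing seed-based fixes orthogonalise signals two
at a time and give a different answer depending on which signal is the
seed.

`leakmend` is for anyone building functional-connectivity networks from
multichannel band-limited signals whose reconstruction step mixes channels
at zero lag. It provides:

* **Symmetric multivariate correction.** For node time-courses
  `Z ∈ R^{m×n}` it finds the closest set of mutually orthogonal
  time-courses `P = OD` minimising `‖Z − P‖²_F`, alternating two closed
  forms: `O ← UVᵀ` from the SVD of `ZD` (the Löwdin orthogonalisation —
  the unique nearest orthonormal matrix) and `d ← diag(ZᵀO)`. The result
  is seed-free, order-free, and minimally displaced from the data.
* **Envelope pipeline.** Zero-phase Butterworth band-pass, Hilbert
  amplitude envelope, 0.5 Hz low-pass, 1 Hz resampling; PCA collapse of
  multi-voxel regions.
* **Network inference.** Full and partial correlations
  (`ρ⊥ = −diag(Ω)^{−1/2} Ω diag(Ω)^{−1/2}`), graphical-lasso precision
  estimation (compiled block coordinate descent) with 10-fold
  contiguous-block cross-validated AICc penalty selection, empirical
  AR(1)-surrogate null calibration of edge z-scores, fixed-effects group
  inference, and Benjamini–Hochberg FDR thresholding.
* **A generative simulator.** Burst-driven linear network dynamics
  (`ȧ = Aa + u + e`, RK4), carrier oscillators at 8–26 Hz, an explicit
  zero-lag Gaussian-profile mixing operator standing in for leakage, exact
  signal-to-noise scaling, and AR(1) null data — so every claim the
  package makes is testable end to end.

## Worked example

```r
library(leakmend)

sim <- simulateExperiment(nNodes = 12, duration = 300, snr = 1, seed = 7)
sim
#> SimulationBundle: 12 nodes x 30000 samples at 100 Hz; 6 true edges, SNR 1, seed 7

bp  <- bandpass(Timecourses(observedData(sim), samplingRate = 100), c(4, 30))
os  <- symmetricOrthogonalise(bp)
os
#> OrthogonalisedSet: 30000 samples x 12 nodes at 100 Hz (300.0 s)
#>   tandem iterations: 5 (converged); final squared error 296.7

max(abs(cor(values(os))[upper.tri(diag(12))]))   # zero-lag correlations gone
#> [1] 3.604886e-08

env <- downsampleEnvelope(hilbertEnvelope(os), band = c(4, 30))
est <- networkEstimate(env, metric = "partial")
z   <- calibrateZ(est, nullScaling(12, nrow(values(env)), envelopeAr1(env),
                                   metric = "partial", seed = 7))
fdr <- fdrThreshold(z, q = 0.05)
fdr$threshold
#> [1] 3.411989
which(fdr$mask & upper.tri(fdr$mask), arr.ind = TRUE)
#>      row col
#> [1,]   1   2
#> [2,]   2   5
#> [3,]   4   5
edgeList(groundTruth(sim))    # the six directed edges actually simulated
#>      from to
#> [1,]    1  2
#> [2,]    2  3
#> [3,]    1  4
#> [4,]    4  5
#> [5,]    3  5
#> [6,]    5  2
```

Every edge surviving the 5% FDR is a true simulated coupling — the
correction has removed the spurious neighbour edges that leakage would
otherwise produce — and the conservative FDR cut keeps the three strongest
of the six true edges in this single 300 s run. Detecting the full set
reliably takes the longer recordings or group pooling used in the
replication studies. The `z` matrix holds calibrated scores (standard
normal on null edges); `fdr$threshold` reports the implied z cut.

The methods vignette (`vignettes/leakage-correction.Rmd`) documents the
model, the tandem algorithm, every tunable parameter with its default and
rationale, the simulator's scope, and the package's two standard
replication studies (`recoveryStudy()`, `fprOrderingStudy()`).

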