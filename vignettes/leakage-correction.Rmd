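---
title: "Symmetric leakage correction and envelope connectomes"
author: "leakmend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetric leakage correction and envelope connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leakmend)
```

## The problem

When many signals are reconstructed from a common set of indirect
measurements — the canonical case being cortical region-of-interest (ROI)
time-courses estimated from magnetoencephalography sensors — the ill-posed
inverse step spreads every true source over several reconstructed signals.
This "source leakage" is linear and instantaneous: it creates
cross-correlations between reconstructed signals at **zero lag only**. Any
amplitude-correlation network analysis run on such signals will report
edges between physically close nodes that share no real interaction.

`leakmend` removes the artefact at its root: it replaces the set of node
time-courses with the *closest set of mutually orthogonal time-courses*, so
that every zero-lag correlation is identically zero, and everything that
survives in the band-limited power envelopes reflects genuine amplitude
coupling (at the acknowledged price of discarding any true zero-lag
connectivity as well).

## The symmetric (tandem) orthogonalisation

For node time-courses $Z \in \mathbb{R}^{m \times n}$ ($m \ge n$, full
column rank) we seek orthogonal columns $P = OD$, with $O^\top O = I_n$ and
$D = \mathrm{diag}(d)$, minimising
$\epsilon = \lVert Z - P\rVert_F^2$. Both conditional problems have closed
forms:

* given $D$, the optimal orthonormal factor is the polar factor of $ZD$:
  if $ZD = U\Sigma V^\top$ then $O = UV^\top$ (the symmetric, or Löwdin,
  orthogonalisation — the unique closest orthonormal matrix);
* given $O$, the optimal magnitudes are $d = \mathrm{diag}(Z^\top O)$.

The tandem algorithm (`symmetricOrthogonalise()`) alternates the two,
starting from $D = I$, so its first iterate is the closest *orthonormal*
set and each later iterate only lowers $\epsilon$. The solution is
unchanged by any reordering of the nodes — unlike Gram–Schmidt, which
privileges whichever node is processed first, and unlike seed-based
pair-wise regression, which gives a different answer for each seed choice.
Convergence is monotone but need not reach the global optimum; in practice
a handful of iterations suffice and the error trace is exposed for
inspection.

Numerical choices:

* **Stopping rule.** Iteration stops when
  $|\epsilon_k - \epsilon_{k-1}| / \lVert Z\rVert_F^2 < 10^{-10}$
  (scale-free), with a cap of 50 iterations. Hitting the cap flags
  `converged = FALSE` on the result instead of raising, so batch studies
  keep running.
* **Rank guard.** Inputs whose singular-value ratio
  $\sigma_{\min}/\sigma_{\max}$ falls below $10^{-10}$ (the double-precision
  SVD noise floor) are rejected: below the rank of the data the closest
  orthogonal set is not unique, which is also why the method cannot be
  pushed to voxel-level (rank-exceeding) analyses.
* **Orthogonality vs correlation.** The algorithm zeroes *inner products*.
  For the sample correlation matrix of $P$ to be exactly diagonal the
  columns must also be zero-mean, which band-passed signals are; the
  pipeline therefore always band-passes before correcting.

## From corrected signals to networks

`powerEnvelope()` implements the standard amplitude-envelope pipeline:
zero-phase 4th-order Butterworth band-pass (8–13 Hz and 13–30 Hz are the
usual rhythms for real recordings; 4–30 Hz for the simulation studies),
Hilbert analytic-signal magnitude, zero-phase low-pass at 0.5 Hz, edge trim
of 1 s, and resampling at 1 Hz. Zero-phase filtering is not cosmetic here:
a causal filter would smear the zero-lag mixing structure across lags and
defeat the correction. The filters are applied forward–backward with
odd-reflection padding and steady-state initial conditions, so a constant
envelope passes through exactly and no multi-second edge transient leaks
into the retained segment; the remaining analytic-transform edge effects
are removed by the 1 s trim. Where a region is represented by many raw
series, `roiTimecourse()` collapses them to the first principal component
of the map-weighted voxel set (weights normalised to peak 1, sign aligned
with the weighted mean).

Envelope networks are modelled as a Gaussian graphical model with
precision $\Omega$; direct connections are the partial correlations
$\rho_{ij} = -\Omega_{ij} / \sqrt{\Omega_{ii}\Omega_{jj}}$
(`partialCorrelation()`). Because inverting a sample covariance is noisy,
`graphicalLasso()` maximises the $L_1$-penalised log-likelihood
$\log\det\Omega - \mathrm{tr}(S\Omega) - \lambda\lVert\Omega\rVert_1$ by
block coordinate descent (compiled; duality gap reported). The penalty
covers the whole matrix including the diagonal, as written above; a
`penalizeDiagonal = FALSE` switch provides the off-diagonal-only
convention used by several other implementations.

### Choosing the penalty

`selectLambda()` uses 10-fold cross-validation on **contiguous temporal
blocks** — envelopes are strongly autocorrelated, and random folds would
place near-duplicate samples on both sides of the split. Each candidate
$\lambda$ (16-point geometric grid on $[10^{-4}, 1]$, zoomed $\times 4$
around the incumbent three times) is scored by a corrected Akaike
criterion on the held-out blocks,
$\mathrm{AICc} = -2\,\ell_{\text{val}} + 2k + 2k(k+1)/(n_{\text{val}}-k-1)$,
with the effective parameter count $k$ equal to the node count plus the
number of nonzero upper-triangle precision entries. The held-out
log-likelihood is pooled over folds and the small-sample correction applied
at the pooled validation size: per-fold corrections at ~60 validation
samples are undefined (or explosive) for any support larger than a couple
of dozen edges and degenerate to empty graphs. Fits whose support exceeds
the pooled validation size are scored $\infty$ — AICc simply does not
exist there. On the package's simulation studies the selected penalties
land at a few times $10^{-2}$, and the fitted support retains the true
edges while pruning most spurious ones.

### Calibration, groups, thresholds

Edge estimates are Fisher-transformed and divided by an **empirical null
standard deviation** (`nullScaling()`): the slow amplitude dynamics make
envelope samples far from independent, so the nominal
$1/\sqrt{m-3}$ spread would be badly anticonservative. The null is built
from independent stationary AR(1) surrogates matched to the envelopes in
node count, sample count and lag-1 autocorrelation (`envelopeAr1()`);
correlations (or unregularised partial correlations) of `nNull = 50`
surrogate datasets are pooled. Matching at the envelope level is the choice
that actually delivers the design goal — calibrated null edges with unit
standard deviation — because surrogates matched to the *raw* band-passed
series have their spectrum re-shaped by the band-pass and cannot represent
smoothness that lives below the band; the package's calibration test
verifies the delivered property directly. Multi-subject inference is a
fixed-effects mean, $z_{\text{group}} = \sum_i z_i/\sqrt{S}$
(`groupFixedEffects()`), and network-level control uses one-sided
Benjamini–Hochberg on the positive-edge p-values (`fdrThreshold()`).

## The simulator

`simulateExperiment()` generates the synthetic recordings used throughout
the tests, emulating the generative model used to validate the method:

* **Ground truth.** A directed network on 5 of the nodes (6 edges in the
  built-in example layout, `defaultNetworkEdges()`), edge weights
  $\mathcal{N}(0.6, 0.1^2)$, system matrix diagonal $-1$ (1 s decay). All
  remaining nodes receive identically generated but uncorrelated dynamics.
* **Drive.** Independent binary burst processes: exponential on/off
  durations with means 2 s and 7 s, amplitude 0.4 while on, initial state
  from the stationary distribution (on-probability 2/9). This
  alternating-renewal reading is the only one consistent with stated mean
  on- and off-times.
* **Dynamics.** $\dot a = Aa + u + e$, integrated by fourth-order
  Runge–Kutta at the acquisition step, with Gaussian input noise
  (variance 0.02) held constant within each step. The equation is treated
  as a noisy ordinary differential equation, not as a formal stochastic
  differential equation — no $1/\sqrt{\Delta t}$ increment scaling — so at
  small steps the burst drive dominates the activity, and that is the
  regime all downstream numbers are reported in.
* **Carriers.** Each node's activity modulates a sinusoid at a distinct
  carrier in 8–26 Hz (evenly spaced by default, random initial phase).
* **Leakage.** Instead of a full sensor-array forward model and
  beamformer (out of scope), leakage is an explicit zero-lag mixing
  operator: nodes sit on a line, row $i$ of the mixing matrix is a
  row-normalised Gaussian profile $\exp(-d_{ij}^2/2\,\text{spread}^2)$.
  The default spread of 0.6 node spacings gives a self-weight of ~0.66 and
  nearest-neighbour weights of ~0.17 — strong local contamination with a
  dominant own-source contribution, the qualitative shape of beamformer
  point-spread. Since real point-spread magnitudes are not printed
  anywhere usable, the spread is an honest free parameter, chosen once.
* **Observation noise.** White Gaussian noise scaled to an exact
  signal-to-noise power ratio (mean-square mixed signal over noise
  variance): 1.0 for the fixed-placement study, 0.4 for the
  random-placement study.
* **Scale.** Recordings default to 600 s at 100 Hz (60 000 samples). The
  carriers fit comfortably under the 50 Hz Nyquist limit, and one
  recording costs about a second to generate.

What the simulator does *not* emulate: sensor geometry and realistic
spatially correlated sensor noise, non-Gaussian artefact sources (blinks,
cardiac), head movement, and the spatially heterogeneous, non-Gaussian
point-spread of a real inverse operator. Passing the package's studies
therefore demonstrates the *algorithmic* claims — exact zero-lag removal,
optimality of the correction, calibration of the null, ordering of the
correction methods — not performance on any particular real acquisition.

## The replication studies

Two study functions reproduce the headline simulation results at desk
scale; the problem sizes are package choices, stated here once:

* `recoveryStudy()` — 15 experiments, 38 nodes of which 5 networked,
  600 s, SNR 1.0, fixed placement, symmetric correction, unregularised
  partial correlations. A repeat counts as *perfect recovery* when one
  threshold separates all 6 true undirected edges from all 697 null edges.
  With chance envelope correlations between independent slow burst
  processes sitting just below the true-edge strengths, most but not all
  repeats separate perfectly (the packaged test requires at least 12 of
  15); the fixed-effects group matrix separates with a wide margin.
* `fprOrderingStudy()` — 20 experiments, 12 nodes of which 5 placed at
  random, 300 s, SNR 0.4, all three corrections on the same recordings.
  The full 38-node version of the pair-wise comparison procedure is
  quadratically expensive (it re-envelopes every node for every ordered
  pair — the reason the original pair-wise approach takes half an hour
  where the symmetric correction takes seconds), so the study uses the
  smaller geometry; the qualitative ordering is unaffected. Expected
  behaviour, verified by the acceptance tests: median empirical FPR at
  $\alpha = 0.05$ inside the binomial band for the symmetric correction;
  FPR(none) > FPR(pairwise) > FPR(symmetric), established by paired
  one-sided Wilcoxon signed-rank tests on the per-repeat rates (the raw
  medians are discrete in units of one null edge and can tie); and a
  further drop under $L_1$ regularisation.

```{r example, eval = FALSE}
cfg <- experimentConfig(nNodes = 12, duration = 300, snr = 0.4,
                        mode = "symmetric", metric = "partial",
                        placement = "random", nRepeats = 5, seed = 1)
res <- runExperiment(cfg)
fprCurve(lapply(res$repeats, `[[`, "z"),
         lapply(res$repeats, `[[`, "trueEdges"))$median
```

## Known limitations

* The correction is exact for zero-lag *linear* mixing; leakage between
  non-Gaussian sources can leave higher-order residuals.
* True zero-lag physiological coupling is removed along with the artefact.
* Nodes dominated by one shared signal become nearly collinear; the
  correction then rotates both heavily and partial metrics behave poorly —
  parcellations should not slice a single functional unit into several
  nodes, and requests below the data rank are refused rather than guessed.
* The pair-wise procedure is retained only as the comparison baseline;
  regularised partials are deliberately not offered for it.
* Per-repeat perfect recovery is a stringent statistic: its limiting
  factor in the simulations is not residual leakage but finite-sample
  envelope correlations between independent slow processes, which only
  longer recordings or group pooling can shrink.
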