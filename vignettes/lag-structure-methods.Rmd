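---
title: "Measuring infra-slow lag structure: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring infra-slow lag structure: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Resting-state BOLD fluctuations below 0.1 Hz are not synchronous across the
brain: activity at one locus systematically leads or trails activity
elsewhere by fractions of a second to a few seconds, far below the sampling
interval of fMRI (TR on the order of 2 s). `boldlag` implements the standard
cross-covariance approach to this problem. For two voxel series
$x_1(t), x_2(t)$ the lagged cross-covariance

$$C_{12}(\tau) = \frac{1}{T}\int x_1(t+\tau)\,x_2(t)\,dt$$

is evaluated at integer frame offsets $\tau_f \in \{-L,\dots,L\}$ (default
$L = 4$ frames, i.e. $\pm 8.32$ s at TR $2.08$ s). Because infra-slow BOLD is
aperiodic, $|C_{12}|$ almost always has a single well-defined extremum. Its
abscissa is refined below the sampling interval by fitting a parabola
through the extremum sample and its two neighbours: with curvature
$c = y_{-} - 2y_0 + y_{+}$,

$$\hat d = \frac{y_{-} - y_{+}}{2c}, \qquad
  \hat\tau = (\text{peak offset} + \hat d)\cdot TR, \qquad
  \hat a = y_0 - \frac{(y_{-}-y_{+})^2}{8c},$$

with $|\hat d| \le 1/2$ guaranteed whenever the middle sample is a weak
extremum of the three. Assembling $\hat\tau_{ij}$ for all voxel pairs gives
the time-delay (TD) matrix, anti-symmetric by construction
($\tau_{ij} = -\tau_{ji}$, zero diagonal): the package computes the upper
triangle and sets the lower triangle to its exact negation, so anti-symmetry
holds to the bit, never merely to tolerance.

Downstream reductions:

* **lag projection** — each voxel's mean lag against all others (row mean of
  TD over valid pairs). The sign convention is $\tau_{ij} > 0$ when voxel
  $i$ is *late* relative to $j$, so projections read negative = early,
  positive = late. Under complete validity, anti-symmetry forces the
  projection to sum to zero.
* **seed lag maps** — each voxel lagged against the mean series of a seed
  region. Voxels inside a large seed may legitimately show non-zero lags
  against the seed mean. An alternative reading (mean over the seed's TD
  columns) is available via `method = "td_column"`; the two agree in rank
  ordering but are not identical, and the reference-series method is
  primary.
* **lag threads** — spatial PCA of the TD matrix after zero-centering each
  column. Invalid entries are imputed by their column mean (zero after
  centering), the least-informative linear completion. Component maps are
  eigenvectors scaled by the RMS projection of the centered columns
  ($\sqrt{\lambda_k}$), placing them on a seconds scale; signs are
  arbitrary and all comparisons are made up to sign.

The number of threads is chosen by the Laplace-approximation evidence for
probabilistic PCA (the standard maximum-likelihood dimensionality
criterion), including a $k = 0$ (isotropic) candidate so a structureless
spectrum is reported as 0 rather than forced to 1. Exactly tied eigenvalues
make the Laplace Hessian singular; such candidates are excluded
($-\infty$ evidence), and exactly low-rank spectra (fewer than two non-zero
eigenvalues) short-circuit to the exact rank.

## Per-epoch preprocessing

The preparation pipeline is detrend → zero-phase low-pass (< 0.1 Hz) →
nuisance regression → frame censoring, each stage optional.

* **Detrending** removes the per-voxel least-squares line over valid
  frames.
* **Low-pass filtering** uses a forward–backward second-order Butterworth
  (effective 4th order). Zero phase is not a nicety here: the measurand is
  a lag, and any phase shift would bias it directly. The series are padded
  by odd reflection at both ends before `filtfilt`, which suppresses edge
  transients while preserving constants and linear trends. Passband gain is
  within 5% below half the cutoff and stopband gain at twice the cutoff is
  below 0.1.
* **Nuisance regression** projects residuals orthogonal to an intercept,
  user-supplied regressors and optionally the global mean signal, over the
  valid frames. Rank-deficient designs fail loudly, naming the collinear
  columns.
* **Censoring** flags frames whose RMS frame-to-frame intensity change
  exceeds a percentage threshold (default 0.5%). A percentage needs a base:
  for raw positive intensities (grand mean exceeding twice the grand SD)
  the epoch grand mean is used; for zero-centered series the conventional
  mode-1000 base applies, so 0.5% is 5 intensity units; an explicit
  `baseline` overrides both. The *later* frame of each super-threshold
  transition is flagged (a single spike therefore flags the spike frame and
  its successor), the first frame is kept by convention, and every maximal
  valid run shorter than 10 frames is removed entirely. An epoch where
  nothing survives is a reportable outcome (`empty` attribute), not an
  error.
* **Censoring stage.** By default the censoring statistic is evaluated on
  the fully processed data. `censor_stage = "detrended"` evaluates it right
  after detrending instead: low-pass filtering smears sharp transients
  below threshold, so scrubbing-style artifact censoring belongs before the
  filter. The analysis workflow uses the pre-filter stage for exactly that
  reason. Gaps are masked, never interpolated; all covariance computations
  run over pairwise-valid frames with per-offset demeaning and a minimum
  overlap of 30 frame pairs per offset.

Estimates whose extremum falls at the window edge have no interpolation
neighbour; they are marked invalid and *excluded* from projections, block
statistics and averages rather than clamped to the window — clamping would
bias group means toward the window width. Exactly flat curvature (a
degenerate parabola) returns the integer-frame lag with a degeneracy flag
rather than an error; it is rare and benign.

## The synthetic forward model

The study conditions are emulated, not downloaded: latent sources with
$1/f^\alpha$ spectra (default $\alpha = 1$) are synthesized on a fine grid
(default $TR/32$), band-limited below 0.1 Hz with an 8th-order rolloff,
mixed into voxels with per-voxel weights, delayed by arbitrary fractional
delays via cubic-spline evaluation, sampled every TR, and contaminated with
white noise. Defaults mirror the sampling regime the method targets: TR
2.08 s and at least 150 frames (five minutes) per epoch.

The band limit deserves emphasis. Sub-sample lag recovery is possible only
when a signal remains correlated across neighbouring frames; a full-band
$1/f$ source decorrelates within one TR once sampled, its cross-covariance
peak becomes a cusp, and no three-point parabola (or any other estimator)
can locate the delay below the frame. The infra-slow band limit is thus the
premise of the whole analysis, and the generator enforces it.

For a single source the ground-truth pairwise lag is the difference of the
planted delays, which is what makes forward/inverse consistency testable:
noiseless single-source epochs must be recovered within $0.1\cdot TR$ across
delays up to $1.9$ s, and at signal-to-noise 5 within $0.25\cdot TR$ mean
absolute error. Both bounds are exercised in the test suite and recomputed
by the acceptance script.

What the generator does **not** emulate: hemodynamic response convolution,
spatial autocorrelation of real BOLD noise, anatomically realistic geometry
(voxels live on a small explicit lattice), physiological nuisance structure,
and subject-level variability beyond independent source realizations.
Passing tests therefore demonstrate the estimators' correctness and
calibration under the stated signal model, not performance on real scanner
data.

Planted-thread TD matrices are built directly in TD space: `k` orthonormal
spatial maps orthogonal to the constant vector, combined with score vectors
whose mixing coefficients are anti-symmetric — the unique construction that
keeps the matrix exactly anti-symmetric while making its column-centered
column space exactly `k`-dimensional. A single delay field is the `k = 1`
special case. Thread powers are drawn comparable (the weakest at least 0.3
of the strongest, by rejection), matching the "equal power" reading of a
planted multi-thread structure; without that constraint a vanishing planted
thread is indistinguishable from noise and the recovery experiment would
measure the draw, not the estimator.

## Two-state statistics

All state contrasts treat the subject-state as the exchangeable unit:
permutations reassign state labels across subjects (within subject when a
subject contributes both states). Every stochastic procedure takes an
explicit seed.

* **Cluster-extent test.** Voxelwise $z$ = difference of state means over
  its pooled standard error; supra-threshold voxels are clustered by
  6-connectivity on the lattice; each observed cluster's extent is referred
  to the permutation null of the *maximal* cluster extent. P-values use the
  $(1+B)/(M+1)$ estimator, which is exact under exchangeability.
* **Block Spearman.** For each of the $m(m+1)/2$ unique network blocks
  (28 for 7 networks, 21 off-diagonal), the Spearman correlation between
  the two states' lag values over the block's valid pairs; the null
  permutes the entry correspondence within the block; family-wise
  correction uses the max-$|\rho|$ statistic across blocks. Significance
  marks blocks whose cross-state correspondence is reliably non-zero
  (preserved structure); blocks with fewer than 10 valid pairs are flagged
  and get no p-value.
* **Block means.** Off-diagonal block means per state (two-stage averaging:
  epochs within subject, then subjects, unweighted by epoch count — an
  epoch-weighted option exists), with the state difference tested by
  subject-label permutation and max-statistic correction over the 21
  blocks. Diagonal-block means are exactly zero by anti-symmetry and are
  asserted, not tested.
* **Lag SD contrast.** Per-subject standard deviation over valid
  upper-triangle TD entries, state difference by label permutation
  (default 10,000 trials). With one subject per state the permutation space
  is degenerate and the p-value is reported as undefined.
* **FC-difference PCA.** Subjects' Fisher-z FC matrices are averaged per
  state, the state-difference matrix is eigendecomposed, and each rank's
  eigenvalue magnitude is compared with the 95th percentile of the
  same-rank permutation null.

### Calibration experiment design

The permutation machinery is audited under the global null: synthetic null
datasets in which both states are drawn from the same generator, with the
family-wise false-positive rate required to sit at $0.05 \pm 0.02$. Two
design choices matter and were fixed before measuring. First, the null maps
for the cluster test are spatially smoothed (Gaussian, 2-voxel FWHM on a
10×10×3 lattice, 8 subjects per state): cluster extents on unsmoothed maps
are tiny integers, and the resulting ties make the test conservative in a
way that measures discreteness rather than calibration. Second, the
cluster-forming threshold for the audit is $|z| = 2.5$ rather than the 4.5
used for reporting effects: with eight subjects per state the voxelwise
statistic is $t$-like, supra-threshold events at 4.5 are so rare that most
null datasets produce no clusters at all, and the audit would again measure
discreteness. Permutation exactness guarantees validity at *any* threshold;
the audit threshold is chosen where the false-positive rate is actually
estimable. The block-mean audit uses random anti-symmetric TD matrices for
both states.

## The reference two-state study

`example_study_design()` plants the three reorganization motifs the
pipeline is meant to expose, on a 4×7×2 lattice (56 voxels, seven named
networks, 8 voxels each; 8 subjects per state, 3 epochs each):

1. a subcortex-analog network shifted 0.4 s early in the wake-like state
   and 0.4 s late in the SWS-like state (seed maps computed against it flip
   sign between states). The network's base delays are centred on the rest
   of the brain so the planted shift — not a random network-mean offset
   amplified by the spread change — determines its early/late position;
2. a visual-analog network uniformly 0.6 s early in the SWS-like state
   (its inter-network block means turn negative along its rows);
3. a doubled delay spread in the SWS-like state (the per-subject lag SD
   roughly doubles and the permutation contrast rejects).

Three epochs per subject are averaged before group statistics, mirroring
the averaging of temporally contiguous epochs in per-subject analysis; with
single epochs the pair-level estimation noise (the dominant error source at
150 frames under a 0.1 Hz band limit) dilutes the SD contrast.

Problem sizes throughout (56-voxel lattice, 60-voxel thread matrices, 500 to
1000 null datasets with 200 permutations each) were chosen so the whole
analysis re-runs from scratch in minutes on one CPU while leaving all
planted effects comfortably detectable.

## Known limitations

* Lag estimates from 150-frame epochs under a 0.1 Hz band limit carry
  substantial sampling noise (few effective degrees of freedom); per-subject
  TD matrices are noisy and the pipeline relies on epoch and subject
  averaging, as the underlying method does.
* The ML dimensionality of *estimated* TD matrices reflects estimation
  noise as well as signal; it is calibrated on planted TD structure, where
  the noise is isotropic by construction, and read qualitatively elsewhere.
* The amplitude accompanying each lag depends on whether curves are
  normalized (correlation) or not (covariance); the lag itself is invariant
  and both variants are provided.
* Real-data ingestion (4D NIfTI plus label volume) is supported, but no
  claims are made about motion correction, registration or other
  scanner-level preprocessing, which are out of scope.
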