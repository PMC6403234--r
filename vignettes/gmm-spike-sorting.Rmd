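---
title: "GMM-based spike sorting: models, parameters and design choices"
author: "gmmsort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GMM-based spike sorting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Extracellular electrodes record the superimposed action potentials of
several nearby neurons. Spike sorting recovers the single-unit activity:
detected waveforms are grouped by shape, under the assumption that each
neuron produces a reproducible extracellular waveform. `gmmsort` implements
an unsupervised sorting framework in which Gaussian mixture models (GMMs)
carry the full weight of the analysis — they estimate per-feature
densities for feature *selection*, the multivariate feature density for
*cluster-number* estimation, and the final *classification* model.

## The mixture model and its EM fit

All stages use the mixture density

$$p(x) = \sum_{i=1}^{k} \alpha_i \, \mathcal{N}(x \mid \mu_i, \Sigma_i),$$

fitted by expectation-maximization. `fitGmm()` runs 10 random restarts
(`nReplicates`) and keeps the highest final log-likelihood. Two restart
initializations exist, chosen per stage. The default (`init = "random"`)
places the means at $k$ distinct observations drawn without replacement,
with the data covariance for every component and uniform weights — a
heavily overlapped start suited to density estimation, and the one the
univariate scoring fits use. The overclustering stage instead seeds each
component inside one k-means cell (`init = "kmeans"`: cell centroids,
within-cell covariances, occupancy weights): started from overlapped
covariances, roughly one fit in ten develops a broad component that
bridges two disjoint clusters, which flattens the density valley between
them and defeats the subsequent peak search; components that start tight
inside one region do not do this. Iteration stops after $10^4$ EM cycles or when the
log-likelihood changes by less than `relTol` percent between cycles. The
default `relTol = 1e-4` percent corresponds to a relative change of
$10^{-6}$, the conventional stopping rule of mixture EM implementations; a
far stricter threshold mainly deepens overfitting of the flat likelihood
ridge (components wandering inside a well-fit cluster) at a large cost in
iterations. Each replicate runs from a deterministic child seed of
`FitOptions$seed`, so every fit is exactly repeatable.

Two numerical safeguards matter in practice:

* **Covariance floor.** Each M-step adds `covarianceFloor` (default
  $10^{-6}$) times the per-dimension data variance to the covariance
  diagonal. Without it, a component can collapse onto a handful of points
  and drive the likelihood toward its singularity.
* **Empty components.** In the fixed-mean variant a component pinned far
  from the data can lose all posterior mass. It is kept alive with weight
  $10^{-12}$ and a floored covariance (with a warning) instead of being
  deleted, because downstream cluster identity depends on the component
  count.

The fixed-mean variant (`fitGmmFixedMeans()`) holds the component centers
at their initial values throughout; only weights and covariances are
updated, and the returned means are bit-identical to the input. This is
the final classification model, with the centers set to the density peaks
found during clustering.

## Features

Three constructions are available:

* **PCA** (`pcaTransform()`): scores on the eigenvectors of the waveform
  covariance, ordered by decreasing eigenvalue. Waveforms are
  column-centered first; each component's sign is fixed so its
  largest-magnitude loading is positive, making runs deterministic.
* **Haar wavelet decomposition** (`haarWd()`): a 4-level multiresolution
  filter bank with the orthonormal ($1/\sqrt{2}$ per level)
  normalization, so the transform is orthogonal — coefficient energy
  equals signal energy and `haarReconstruct()` inverts it exactly. Those
  two properties are the testable contract of the implementation.
  Multi-channel waveforms are decomposed per channel and concatenated. A
  snippet length that is not a multiple of $2^4$ is padded by reflecting
  its tail; coefficients whose support touches padding are flagged in
  `featureInfo` but kept (they still carry shape information). The
  level-4 approximation coefficients are kept among the candidates, so
  the candidate set has exactly as many coefficients as samples.
* **Weighted PCA** (`weightedPca()`): every wavelet coefficient is
  z-scored, multiplied by a GMM-based separability score, and the product
  decomposed by PCA. Z-scoring makes the weights the sole carrier of
  between-coefficient importance, which is why the raw-variance metric is
  rejected for wPCA — it would exactly undo the z-scoring.

## Separability metrics and feature selection

For each candidate feature an 8-component univariate GMM is fitted to the
empirical distribution (`scoreFeatures()`), and one of three scores is
derived:

* `i_peak` / `i_inf`: the fitted density is discretized on 100 equally
  spaced points over the data range; peaks are sign changes of the first
  finite difference, inflection points sign changes of the second. The
  score is the summed density at those points normalized by the maximum
  density — roughly, the number of modes (or shoulders) the feature
  resolves. A plateau in the discretized density counts once, at its left
  edge.
* `i_dist`: the median over all component pairs of
  $D_{ij} = |\mu_i - \mu_j|\sqrt{\alpha_i\alpha_j} / (\sigma_i\sigma_j)$ —
  how far apart two Gaussians are in units of their spreads, weighted by
  how much data they carry.
* `var`: the raw variance (the classical PCA ranking; no GMM).

The 5 highest-scoring features (`selectTop()`, ties to the lower column
index) enter clustering; for wPCA the first 5 weighted PCs (variance
order) are used directly.

Two properties of `i_dist` are worth knowing. First, it is not
scale-free: $D_{ij}$ has dimension 1/x, so multiplying a feature by $a$
divides the score by $a$ (shifts leave it unchanged). Inside wPCA this is
irrelevant because coefficients are z-scored first; when comparing raw
features, compare like with like. Second, its value on *unimodal* data is
small but not zero (typically 0.1–0.2): EM leaves the 8 component means
spread along the flat likelihood ridge, so pair distances do not vanish.
The metric is a ranking device — multimodal features score above unimodal
ones — not a calibrated distance; on extreme, perfectly balanced
two-cluster data its median-of-pairs construction can even fluctuate with
how many components land on each cluster. The tests assert the ranking
behavior the pipeline relies on, and the idealized monotone-in-separation
property is checked at its face value in the acceptance suite.

Univariate fits subsample features to at most 50 000 points (seeded) —
well above the spike counts the pipeline sees in practice.

## Clustering

Clustering proceeds in three steps on the 5 selected features:

1. **Overclustering** (`overcluster()`): a full-covariance GMM with more
   components than plausible neurons — 12 by default (single wire), 20
   for tetrode-style concatenations. Surplus components act as a
   smoothing of the density estimate rather than as clusters.
2. **Density-peak search** (`findDensityPeaks()`): one Nelder-Mead
   simplex run per component, started at the component center, maximizing
   the mixture density (minimizing its negative log; 2000 evaluations,
   relative tolerance $10^{-10}$; in one dimension the simplex degenerates
   and a quasi-Newton climb is used instead). Non-converged searches are
   discarded with a warning. Endpoints are then merged in three stages:
   * *distance merge*: endpoints whose range-normalized Euclidean
     distance (each coordinate divided by that dimension's data range) is
     below 1% are the same peak. A per-axis variant of this rule is
     available via `mergeMode = "per_axis"`.
   * *valley merge* (`valleyThreshold`, default 0.2): two peaks whose
     connecting segment never drops below 0.2 of the lower peak density
     are ripples of one connected high-density region, not separate
     modes. Finite-sample mixture fits of a single well-populated cluster
     routinely show such shallow lobes; measured on synthetic
     well-separated clusters, within-cluster lobe pairs have valley
     ratios of 0.3–0.95 while true between-cluster valleys are below
     $10^{-7}$, so any threshold within an order of magnitude of the
     default behaves identically.
   * *mass filter* (`minPeakMass`, default 0.02): a retained peak must
     attract at least 2% of the total mixture weight (summing the weights
     of the components whose searches converged to it). This removes
     isolated "needle" modes contributed by tiny-weight components, which
     carry at most ~1% of the mass. The highest-mass peak is always
     retained.

   Each retained mode is located at the weight-weighted mean of its
   constituent components' centers — the aggregate's mode estimate —
   rather than at whichever finite-sample ripple a search happened to
   stop on; on synthetic clusters this lands within ~0.1 standard
   deviations of the true center, whereas individual ripple endpoints
   miss by up to 2.
3. **Fixed-mean classification** (`classifySpikes()`): a fixed-mean GMM
   with one component per retained peak; every spike is assigned to the
   component of highest posterior probability (exact ties to the lower
   cluster index).

Deliberate overclustering plus peak merging estimates the *mode* count of
the density, which is robust to the exact number of mixture components —
the package asserts peak-count invariance across 8/12/16 components in
its tests. Genuinely split clusters (e.g. bursting neurons whose
amplitude varies) may still produce more modes than neurons; merging such
clusters is an explicit post-processing action (`mergeClusters()`, or the
`merge` CLI verb), never a heuristic.

### Outlier handling

With `sortSpikes(..., outlierHandling = TRUE)`, spikes whose distance to
their 20th nearest neighbor (in the full coefficient space) exceeds twice
the 95th percentile of those distances are excluded from every mixture
fit, and are assigned at the end by the final fixed-mean model (template
matching by model density). Both the neighbor order and the cutoff are
configurable and recorded in the result's configuration; the defaults are
the package's own choice.

## Preprocessing

Raw traces are band-pass filtered at 300–3000 Hz (4th-order zero-phase
Butterworth, forward-backward) and thresholded at `thresholdSd` (3–7,
default 5) robust standard deviations per channel. The SD is estimated by
MAD $\times$ 1.4826 so that the spikes themselves do not inflate the
threshold (plain SD available by flag). Detection is negative-going by
default; each event is cut as a 64-sample snippet centered on its
extremum, channels concatenated in recorded order for multichannel
groups. A 1 ms lockout prevents re-triggering inside one suprathreshold
excursion, and a non-maximum suppression over one snippet length removes
re-detections of the filter undershoot that trails large spikes — two
extrema within one window necessarily describe the same event.

Ground truth is attached by `matchGroundTruth()`: a truth event with
exactly one detection within 2 ms transfers its label; with more than one
candidate it is ambiguous and discarded; with none it is a miss.
Unmatched detections are labeled background (0).

## Evaluation

Performance against ground truth is measured on the true-by-assigned
contingency table: plug-in mutual information in bits, and its normalized
form $MI_{norm} = 100 \, MI(X,Y)/H(X)$ — the percentage of spike identity
information the sorting extracts. $MI_{norm}$ is invariant to relabeling
and to splitting a true class across clusters, which suits an
overclustering pipeline; the error rate (predominant-neuron rule) is
reported alongside. The plug-in estimator carries no bias correction by
default (at these spike counts the bias is far below the reported
precision); a Miller–Madow flag exists. `consistency()` summarizes
repeated runs (mean and variance of $MI_{norm}$, mean cluster count), and
`symmetrySweep()` reruns the pipeline with one class subsampled to each
symmetry index, reporting both overall $MI_{norm}$ and the
subsampled-class-versus-rest $MI_{norm}$ (all other classes joined), the
quantity that exposes how rare units get absorbed by large ones.

## The simulator

`synthesize()` builds recordings with known ground truth. Templates are
parametric biphasic/triphasic shapes (Gaussian trough, delayed
after-hyperpolarization bump, optional pre-spike positivity) with trough
widths spanning roughly 0.3–1.2 ms, peak-normalized with the unit peak at
the trough; target templates are rejection-sampled to a minimum pairwise
L2 distance of 0.5 so the neurons are genuinely distinct shapes. The
background is low-amplitude spikes drawn from the non-target templates
(default 20 Hz at ~1.5 noise SD) superimposed on white Gaussian noise;
target spike trains are Poisson with a 2 ms refractory floor, and target
amplitudes are set to `snr` times the measured background SD, so the
injected amplitude ratio is exact by construction. The default conditions
are three neurons at 5 Hz for 60 s at 24 kHz with SNRs (6, 9, 12) — the
per-neuron SNRs deliberately differ, as they do across units of a real
recording. Coincident-spike outliers (two target spikes within 0.5 ms,
waveforms summed) are injected with probability `outlierFraction`.

What the simulator does *not* emulate: electrode drift and waveform
nonstationarity, bursting amplitude attenuation, correlated (non-Poisson)
firing, spatial overlap across high-density arrays, and real template
shape families beyond the parametric one. Passing tests on these
simulations therefore demonstrate the machinery — detection, feature
scoring, mode finding, classification, evaluation — under controlled
conditions, not performance on any particular real preparation.

The `"waveforms"` output mode skips the continuous trace and emits
labeled snippets directly (template + unit-SD noise); the noise and
asymmetry sweeps use it because they do not exercise detection.

## Problem sizes in the validation suite

The validation suite sorts one 60 s simulated recording (about 900
target spikes) 25 times per strategy for the consistency comparison (the
standalone reproduction script uses a 30 s recording for the same
25-run protocol); 20 seeded 3-cluster datasets (400 points per cluster,
6-sigma separation) for cluster-number recovery; a 5-level SNR sweep at
30 s; and a symmetry sweep at 60 s with 20 Hz firing so that a 1% index
still leaves at least 10 spikes. These sizes keep every property
measurable at desk scale while leaving each experiment's statistics
(CLT-level tolerances, 19/20 seed criteria) meaningful.

## Known limitations

* Mode counting on a finite-sample mixture density depends on the
  significance filters described above; pathological geometries (nested
  or strongly non-convex clusters) are outside the model class. The
  valley merge cannot distinguish two clusters closer than roughly
  3.5 within-cluster standard deviations from two ripples of one cluster
  — their valley depths overlap — so such near clusters are occasionally
  reported as one mode. The recourse is the same as for any contested
  boundary: inspect the contingency/posterior structure and split or
  merge explicitly.
* `i_dist` rankings are reliable for moderately separated multimodal
  features; on perfectly balanced, extremely separated synthetic features
  the median-of-pairs statistic is allocation-sensitive (see above).
* The detector resolves no overlapping spikes; coincident events appear
  as one detection (and are discarded from ground-truth matching by the
  2 ms ambiguity rule).
* Univariate scoring fits inherit EM's restart stochasticity; scores are
  reproducible only through the seed plumbing, which the pipeline applies
  throughout.
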