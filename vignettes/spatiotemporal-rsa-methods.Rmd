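---
title: "Spatiotemporal RSA: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal RSA: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatempRSA)
```

## The scientific problem

Primary motor cortex (M1) does not map the body part by part; it encodes
movements through distributed activity patterns. Two competing accounts of
what those patterns represent are *kinematics* (the motion of the hand —
joint displacements over time, without reference to the forces that produce
them) and *muscle activity* (the pattern of muscular contraction that
produces the motion). Because every movement generates both, the two are
confounded in any single recording modality: dissociating them requires
asking **where** in cortex and **when** relative to movement onset each kind
of information is encoded. Kinematic structure appearing *before* movement
onset argues for a role in top-down motor planning; muscle-like structure
appearing late after onset is more consistent with bottom-up somatosensory
feedback.

`spatempRSA` implements the full representational similarity analysis (RSA)
machinery for this question: candidate *model* representational
dissimilarity matrices (RDMs) built from peripheral recordings (a 14-channel
kinematic data glove, 15-channel surface EMG, an ethological action
taxonomy), *data* RDMs built from brain recordings with cross-validated
Mahalanobis (crossnobis) distances, a surface searchlight analysis with
omnibus (max-statistic) permutation thresholds for the spatial question, and
a sliding-window analysis with cluster-based permutation inference for the
temporal question. Because no recordings are distributed with the package,
every stage is validated on synthetic data with a *planted* representational
geometry that the pipeline must recover.

## Model RDMs

The condition set is a repertoire of 26 naturalistic hand movements
(pinches, whole-hand grips, single- and multi-digit flexions, thumb
movements; `movement_set()`).

**Kinematic and muscle models.** For each condition pair, each channel's
trial-averaged timecourses are Pearson-correlated; per-channel correlations
are Fisher z-transformed (`atanh`), averaged across channels, transformed
back, and the dissimilarity is $1-\bar r$ (`channel_correlation_rdm()`).
Correlations of exactly $\pm 1$ are clipped to $\pm(1-10^{-10})$ before
`atanh` so noiseless fixtures stay finite; channels with constant
timecourses are dropped from the affected pair with a warning. EMG channels
are additionally noise-normalized across channels before correlation
(`mnn_trials()`), because electrode noise is strongly correlated across
nearby muscles.

**Ethological model.** A categorical RDM (`ethological_rdm()`): 0 within a
category (precision prehensile / power prehensile / nonprehensile), 1
across. The numeric coding is binary by default and configurable
(`between_value`), since nothing forces the two prehensile subcategories to
be nearer each other than to nonprehensile movements.

**Onset alignment.** Epochs are aligned to movement onset detected from the
earliest channel crossing of an adaptive Hilbert-envelope threshold
(`detect_onset()`, `earliest_onset()`): the analytic-signal envelope
(mirror-padded FFT Hilbert transform, median-subtracted) is smoothed over
5 ms, thresholded at the lower-quartile envelope level plus one standard
deviation (recomputed per trial — "adaptive"), and a candidate onset must
stay suprathreshold for at least 200 ms. The returned onset is refined to
the steepest envelope rise inside the qualifying segment, because the
smoothed envelope of an abrupt onset begins rising before the onset itself
(a Hilbert-transform precursor); without refinement step onsets are
systematically early by tens of milliseconds. Onsets from a second modality
can be cross-validated with `validate_onsets()` (default exclusion beyond
±100 ms).

**Display utilities.** `cluster_order()` gives a deterministic
average-linkage leaf order (ties broken by lowest condition index, so an
all-equal RDM yields the identity permutation — `stats::hclust` makes no
such guarantee, which is why the agglomeration is implemented in-package).
`mds_embed()` is metric stress-majorization (SMACOF-style Guttman
transforms) rather than classical eigendecomposition MDS; the first start is
the classical solution, the remaining 99 are random, and the best stress
wins. Stress is reported as normalized Kruskal stress-1.

## The crossnobis core

For features $V$ and GLM residuals $R$ ($T \times V$), the noise covariance
is $\hat\Sigma = \tfrac1T R^\top R$ (`estimate_noise_cov()`), optionally
shrunk towards its diagonal. Shrinkage defaults to an analytic
(Ledoit–Wolf-style) intensity — the ratio of the summed sampling variances
of the entries to their summed squares — because searchlight-sized $V$
routinely approaches or exceeds $T$ and the raw estimate is then singular; a
relative eigenvalue floor of $10^{-8}\lambda_{\max}$ is applied at
inversion. Patterns are prewhitened as $P^{*} = P\,\hat\Sigma^{-1/2}$
(`whiten_patterns()`, symmetric inverse square root).

The crossnobis distance between conditions $k, l$
(`crossnobis_rdm()`) multiplies the whitened pattern difference measured in
one fold with the same difference measured in held-out data:
$d^2(k,l) = (P^{*}_k - P^{*}_l)_A \,(P^{*}_k - P^{*}_l)_B^\top / V$.
Because the two factors carry independent noise, the estimator is unbiased:
its expectation is zero when the condition means are identical, and
estimates can legitimately be negative. Two fold schemes are provided: each
fold in turn against the mean of the others (default, matching a
leave-one-run-out design) and all unordered fold pairs; the default follows
the one-run-versus-rest reading of cross-validated distance estimation, and
the alternative is exposed because "all possible pairs of folds" is also a
defensible reading. Distances are divided by $V$ (configurable) so values
are comparable across searchlights of different sizes.

Model comparison uses Spearman rank correlation over the lower-triangle
entries (`spearman_rdm()`), which imposes no distributional assumption and
therefore permits comparing models built from different source data; ties
get average ranks. `partial_spearman_rdm()` rank-transforms all three RDM
vectors and computes the partial Pearson correlation, used to assess the
kinematic model while discounting the muscle model and vice versa. The
noise ceiling (`noise_ceiling_upper()`) is the mean Spearman correlation of
each subject's RDM with the cross-subject average; since each subject is
included in the average this is an upper bound (the package also ships the
leave-one-out lower bound as a descriptive utility).

## Spatial analysis

`fit_glm()` models each condition with a boxcar convolved with a
single-gamma HRF (shape 7, scale 1 s — peak at 6 s, no undershoot) plus its
temporal derivative: 52 condition regressors for 26 conditions, plus an
intercept, estimated by OLS. No autoregressive prewhitening is applied in
the GLM; the synthetic AR(1) noise therefore mildly violates OLS
assumptions, which is acceptable for rank-based (ρ-level) analyses and is a
deliberate simplification.

`build_searchlights()` collects, per vertex, the features of all vertices
within half the searchlight diameter (default 10 mm) by graph-geodesic
distance along mesh edges. Geodesic membership replaces the gray-matter and
trans-sulcal masking a real surface pipeline would do in volume space; the
mesh's `feature_map` abstraction carries that responsibility here.

Inference (`omnibus_threshold()`): per permutation, the condition labels of
each searchlight's data RDM are permuted (rows and columns; one shared
permutation across the map per iteration) and the spatial maximum ρ
recorded; the threshold is the $\lceil \alpha N \rceil$-th largest of the
max distribution (defaults $N = 10\,000$, $\alpha = 0.01$), which controls
the family-wise error across vertices. Permuting the data RDM is equivalent
to shuffling condition labels before distance computation only under the
null, which is exactly where the threshold is computed; it avoids refitting
distances per permutation. Group summaries: `group_heatmap()` counts
suprathreshold subjects per vertex; `contrast_model_maps()` runs a
one-sided Wilcoxon signed-rank test on subject-wise ρ differences per
vertex with Benjamini–Hochberg FDR (default α = 0.05). The signed-rank null
is computed exactly by dynamic programming over sign flips (average ranks
for ties), because the classical exact distribution is unavailable under
ties yet tied differences are exactly the case the contrast must handle
(all-zero difference vertices get p = 1).

## Temporal analysis

Band-pass filtering (`bandpass()`) uses the squared-magnitude (zero-phase)
response of a 4th-order Butterworth design, applied spectrally to all
trials and channels at once; band presets are alpha 7–14, beta 15–30, gamma
30–100, broadband 7–100 Hz (a 5–100 Hz broadband variant is available as an
explicit numeric band). Baseline correction subtracts the per-trial,
per-channel mean over a fixation window. Trials are split into 10
partitions per condition (seeded shuffle, sizes differing by at most one)
and averaged within partition (`partition_average()`); partition means are
the cross-validation folds.

`sliding_rdms()` moves a 20 ms window in 5 ms steps across the epoch under
an end-strict convention — a window `[s, s + w)` is kept only if its end
falls strictly before the epoch end — chosen because it yields exactly 396
windows on the 2 s epoch, the count the analysis is built around (inclusive
enumeration would give 397). Features per window are the concatenated raw
filtered samples of all sources (amplitude envelopes were considered and
rejected as the default because the raw signal is the more literal reading
of "the frequency-filtered signal"; envelope features can be emulated by
filtering upstream). Source-level noise normalization estimates the error
covariance across sources from partition-level deviations around condition
means, pooled over the epoch, with triangular (Cholesky) whitening.

`cluster_inference()` shuffles the *model* RDM's condition labels (1000 by
default), recomputes the correlation timecourse per shuffle, forms the
per-window cluster threshold at the $1-p_{\text{cluster}}$ null quantile
(default 0.01), and compares each observed cluster's mass (sum of ρ over a
maximal suprathreshold run) against the null distribution of the maximum
cluster mass (significance at α = 0.001 by default). The statistic is
cluster mass rather than extent; the analysis is one-sided (positive
encoding). `temporal_noise_ceiling()` applies the upper-bound ceiling per
window.

## The synthetic-data generators

The generators are first-class, tested code: they define the conditions
under which the pipeline's claims are verified.

**Planted geometry.** `plant_condition_patterns()` embeds a target RDM
(squared distances) into feature space by classical scaling — exact up to
numerical precision — with a seeded random rotation to spread signal over
all features. The correlation-RDM generators use an equal-norm variant
(Gram matrix $c\,\mathbf{1}\mathbf{1}^\top - D/2$): equal pattern norms
make Pearson correlations *exactly* affine in the planted distances, so the
kinematic/muscle model RDM recomputed from noiseless output has Spearman
ρ = 1.0 with the target, ties included. Because that Gram matrix is never
positive semi-definite at finite $c$ when the target geometry is
rank-deficient, the target is first blended (weight 0.25) towards a simplex
geometry — a uniform additive shift of all squared distances, strictly
monotone and therefore rank-preserving — which keeps $c$, and with it the
spread of the resulting $1-r$ values, in a realistic range
(max $1-\bar r \approx 0.9$).

**Glove and EMG.** Condition templates are sums of raised-cosine bumps over
the movement period (1.6 s movement + 0.8 s rest at 60 Hz for the glove;
2.0 s post-onset epochs for EMG, nonnegative with a configurable baseline,
native 2048 Hz with a decimation option), with equal-norm embedding
coefficients; every channel carries an affinely rescaled copy, and trials
add i.i.d. Gaussian noise. Sessions follow the behavioral block structure
(one block per condition per run, randomized order).

**fMRI-like.** `gen_fmri_session()` plants betas realizing the target RDM
in a vertex patch of a mesh (pure-noise betas elsewhere, amplitude-matched)
and generates series as design × betas + AR(1) noise (coefficient 0.3 — a
typical single-TR autocorrelation; nothing in the protocol pins it down, so
it is fixed once here). The mesh fixture is an icosphere
(`icosphere_mesh()`); Euclidean edge lengths stand in for cortical geodesic
distance, and the sphere radius controls how many vertices a 10 mm
searchlight covers. Default block timing: 17 s blocks, TR 1.5 s.

**MEG-like.** `gen_meg_session()` adds, inside the plant window only, a
condition-amplitude-modulated carrier (sinusoid at the plant band's centre
under a raised-cosine taper, then zero-phase band-limited — an unfiltered
120 ms tapered sinusoid has a spectral main lobe wide enough to leak
condition structure into neighbouring bands) on top of 1/f-amplitude
background noise. The background amplitude is a fixed constant (100 ×
`noise_sd`), calibrated once so that at the default conditions
(26 conditions, 31 sources, 50 trials per condition, 600 Hz) the planted
effect at `signal_scale = 1` produces a single-session model-correlation
peak near 0.3 — a realistic effect size for time-resolved RSA.

**What the generators do not emulate.** No biomechanics, no MEG
forward/inverse physics, no scanner artifacts, no trial-to-trial amplitude
or latency variability, no spatially correlated fMRI noise beyond AR(1) in
time. Passing recovery tests therefore demonstrates that the *estimators
and inference procedures* are correct and calibrated under controlled
conditions — not that real recordings would yield the same effect sizes.

## Problem sizes used in the validation suite

The test suite and the acceptance script validate error control and
recovery at reduced problem sizes chosen once: spatial simulations use a
42-vertex icosphere (radius 8 mm, so a 10 mm searchlight spans a vertex and
its 1-ring), 12 conditions from a 3-dimensional planted geometry, 4 runs,
and 500-permutation omnibus thresholds over 100–200 replicates; temporal
recovery uses 26 conditions, 16 sources at 250 Hz over a
[-500, 500) ms epoch with 20 trials per condition, 200 model shuffles and a
cluster family-wise level of 0.005; temporal type-I simulations use 12
conditions, 8 sources at 200 Hz over [0, 400) ms. Noise levels for the
scaled temporal runs (`noise_sd = 0.25`) were fixed alongside those sizes so
that the planted beta-band window is recovered with a comfortable margin
while the gamma-band analysis of the same data stays null.

## Numerical choices and degenerate inputs

* Fisher z at $r = \pm1$: clip to $\pm(1-10^{-10})$.
* Covariance inversion: relative eigenvalue floor $10^{-8}\lambda_{\max}$;
  singular covariances with zero shrinkage are rejected with a pointer to
  shrinkage.
* `mnn_trials()` whitens with the inverse lower Cholesky factor rather than
  the symmetric inverse square root: any whitening yields identical
  crossnobis distances (they depend only on $\hat\Sigma^{-1}$), but only
  triangular whitening makes the normalized signals themselves invariant to
  per-channel rescaling. Spatial prewhitening of fMRI patterns
  (`whiten_patterns()`) keeps the symmetric root.
* Rank ties: average ranks everywhere.
* All-zero RDMs embed to coincident points; constant model RDMs are
  rejected where a rank correlation would be undefined.
* Every stochastic step takes an explicit integer seed and restores the
  caller's RNG state; identical seeds give bit-identical outputs.

## Known limitations

* The searchlight permutation scheme permutes the data RDM rather than
  refitting distances per shuffled labelling; the two coincide under the
  null but not under the alternative (where only the null matters for the
  threshold).
* The noise ceiling's upper bound includes each subject's own data in the
  group average and is therefore optimistic on pure noise; it is reported,
  not corrected.
* The behavioral protocol's printed per-run duration and its printed 5-run
  total are mutually inconsistent; the package follows the per-block
  arithmetic (23.2 s × 26 blocks = 603.2 s per run) throughout.
* Temporal-window features are raw filtered samples; phase-locked and
  induced activity are therefore weighted differently than envelope-based
  features would weight them.
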