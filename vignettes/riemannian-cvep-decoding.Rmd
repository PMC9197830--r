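---
title: "Riemannian transfer learning for c-VEP decoding: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Riemannian transfer learning for c-VEP decoding: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The decoding problem

A code-modulated visual evoked potential (c-VEP) speller flickers every
target with the same pseudorandom binary sequence, each target at a distinct
circular time lag. A 63-bit maximum-length sequence (m-sequence) presented at
a 60 Hz refresh gives one stimulus cycle of 63/60 = 1.05 s; 16 targets
separated by 4-bit lags use 64 of the 63 available bit positions modulo the
period, which still yields 16 pairwise-distinct codes. Because every class is
the *same* waveform at a different lag, the spatial covariance of a trial
carries no class information at all — classes differ only in trial--template
temporal alignment.

The decoder therefore works on **super-trials**: the vertical stack of all
`Z` class-template signals on top of the trial,
`X' = [X̄_1; …; X̄_Z; X]`, an `Nc(Z+1) × Nt` matrix. Its sample covariance
(`X'X'ᵀ/(Nt−1)` after row centering) embeds the cross-covariance between the
trial and every template; for the true class that block is (close to) the
signal autocorrelation at lag zero, for other classes it is the
autocorrelation displaced by the lag difference. Classification is minimum
distance to mean (MDM) on the manifold of symmetric positive definite (SPD)
matrices: each class is summarized by the log-Euclidean mean of its training
super-covariances and a test covariance is assigned to the nearest mean.

With 9 channels and 16 targets the super-covariance is 153 × 153 while one
cycle at the simulation rate has only 630 samples, so the raw estimate is
ill-conditioned. Shrinkage replaces it by `λΓ + (1−λ)P`. Three targets `Γ`
are implemented: identity scaled by the full trace, identity scaled by the
average eigenvalue, and the diagonal of `P` (unequal variances, off-diagonals
shrunk toward zero). The diagonal target is the default. When no fixed `λ` is
given, the analytic intensity is used: the ratio of the summed estimated
sampling variances of the covariance entries to the summed squared deviations
from the target, restricted to the off-diagonal entries for the diagonal
target and clipped to `[0, 1]`. Any `λ > 0` makes the estimate strictly
positive definite, since every target is positive definite and the
combination is convex. A fixed `λ` may take either endpoint: 0 returns the
sample covariance, 1 returns the target.

## Geometry

Two Riemannian distances are provided. The affine-invariant distance
`d_AI(P1, P2) = ‖log(P1^{-1}P2)‖_F` is invariant under congruence by *any*
invertible matrix; the log-Euclidean distance
`d_LE(P1, P2) = ‖log P1 − log P2‖_F` is invariant under orthogonal congruence
(and agrees with `d_AI` on commuting pairs). The corresponding means are the
geodesic midpoint / Karcher fixed point for the affine-invariant metric and
the closed form `exp(N^{-1} Σ log P_i)` for the log-Euclidean metric. The
`1/N` normalizer is essential — without it the "mean" of `N` copies of `P`
would be `P^N` — and the implemented form is the exact minimizer of the
summed squared log-Euclidean distances, which the test suite verifies
numerically against random perturbations.

MDM uses log-Euclidean class means; the distance applied at classification
time is log-Euclidean by default, keeping metric and mean consistent, with
the affine-invariant distance selectable
(`experiment_config(metric = "affine_invariant")`). In the log-Euclidean
route every covariance is mapped through the matrix logarithm once and all
downstream operations (means, pooling, distances) are Euclidean in log space,
which is what makes the leave-one-subject-out sweeps tractable.

Eigenvalues below `1e-12` times the largest eigenvalue are floored there
before any matrix logarithm or inverse square root; genuinely indefinite
input (smallest eigenvalue below `−1e-8` relative) is an error, not a repair.
The affine-invariant mean iterates the standard fixed point from the
log-Euclidean mean and declares convergence when the Riemannian gradient norm
falls below `1e-9` (at most 100 iterations).

## Alignment and transfer

Cross-subject transfer pools labelled covariances from source subjects with
the target's own (few) training covariances. Two mechanisms fight the
between-subject distribution shift:

* **Log-Euclidean data alignment (LEDA).** The reference matrix is the
  inverse square root of the log-Euclidean mean of the trials' sample
  covariances; trials are aligned by left-multiplication, `X' = M_ref X`, so
  covariances transform by congruence and each subject's data are whitened
  toward a common frame. Labelled data (source trials, the target's training
  trials) are aligned per class; the target's unlabelled test batch is
  aligned by one global reference. For c-VEP data the per-class references
  are nearly identical anyway — the raw spatial covariance is almost
  lag-invariant — which is why mixing supervised and unsupervised alignment
  across training and test data is benign here.
* **Training-accuracy-based subject selection (TSS).** Source subjects are
  ranked by the accuracy that an MDM model trained on that source alone
  achieves on the target's training covariances; the top-`c` pools are then
  retrained for `c = 1 … n_sources` and the pool size with the highest
  training-set accuracy wins, ties going to the smallest pool. The final
  transfer model pools the selected sources with the target's training data.

The evaluation harness (`run_loso`, `run_loso_suite`, `sweep_loso`) runs the
four pipelines — SSL (target data only), TL-ASS (all sources, no alignment),
TL-LEDA-ASS (all sources, aligned), TL-LEDA-TSS (selected sources, aligned)
— under leave-one-subject-out cross-validation, with sweeps over data length
(stimulus-cycle multiples), channel-count prefixes and training-trial counts.
Wolpaw's information transfer rate uses the selection time
`T = k · 1.05 s + 1 s` of gaze shifting; accuracies at or below chance report
0 bits/min with the raw (negative) value kept as an attribute. Paired
two-sided t-tests across subjects (`compare_loso`) are reported without
multiple-testing correction, matching the single-comparison reporting
convention of the evaluation design.

## Design decisions that were genuinely open

**Whose templates enter a source subject's super-trials.** Processing each
source entirely in its own frame (own templates) needs no target data, but
the template blocks dominate the super-covariance, so source class means and
target test covariances then live in systematically different regions of the
manifold; on synthetic data this mismatch collapsed every transfer pipeline
below the subject-specific baseline. The default is therefore to build
source super-trials with the *target's* templates, which places all pooled
covariances in one feature-space geometry; `source_templates = "own"` keeps
the target-free variant available. A related subtlety: when templates are
averaged from the very trials that become covariances, each covariance
acquires a `1/n`-weighted noise self-match at its own class's template block
— a universal class signature that saturates any training-set accuracy
criterion. The target's training covariances unavoidably carry it (the
target has no other data), but source covariances must not, or TSS cannot
discriminate between sources.

**What the TSS inner loop trains on.** Retraining the top-`c` pools *with*
the target's training covariances makes the inner criterion a resubstitution
estimate — it saturates at 1 for every `c` and the smallest-`c` tie rule then
always selects a single source. The default therefore retrains on source
data alone, keeping the target's training set a held-out yardstick;
`pool_target = TRUE` restores the pooled variant.

**Where alignment happens.** The pipeline aligns raw `Nc × Nt` trials, then
rebuilds templates from aligned trials, then stacks super-trials
(`alignment_stage = "raw_trials"`). Aligning the stacked super-trials
instead is available as `alignment_stage = "super_trials"`; it is
substantially more expensive (the references are `Nc(Z+1)`-dimensional) and
is retained as a configuration, not a default.

**Filtering.** Butterworth band-pass 2–30 Hz of (overall) order 8, applied
zero-phase (forward–backward) by default as is standard for offline
analysis; a causal single pass is available for online use. The filter is
applied to trials before any shifting or covariance estimation; shifting
after filtering and filtering after shifting differ only in edge effects,
identically for training and test data of a class.

**Shift direction.** Target `z` is the base code rotated *right* by
`(z−1)·τ_s` bits (later target ⇒ larger delay), and training trials recorded
at the reference target are rotated right by `(z − reference)·τ_s` bits to
synthesize class `z`. Only relative lags matter to the decoder, so the
opposite convention would merely relabel classes. Which degree-6 primitive
polynomial and register seed generated the original 63-bit sequence is not
recoverable from the published design; the default taps are `{6, 5}`
(`x^6 + x^5 + 1`), primitivity is verified at run time by measuring the
register period, and any primitive choice reproduces every property the
pipeline uses (length, balance, two-valued autocorrelation).

## The synthetic population

Real multi-subject c-VEP recordings are not redistributable, so the package
ships a generator that reproduces the statistical structure the decoder
relies on, with the reference design as defaults: 16 subjects, 9 channels,
the 63-bit/16-target/4-bit-lag codebook, 100 reference-target training
cycles and 5 test trials per target, one trial = one stimulus cycle.

Each subject is a linear code-locked system: a difference-of-gamma evoked
kernel (positive peak near 100 ms, weaker rebound near 220 ms) circularly
convolved with the ±1 code waveform, projected to channels through an
occipital-like topography, plus i.i.d. Gaussian channel noise, all passed
through a subject-specific symmetric positive definite channel transform
`I + s·A_sym` (`shift_strength`, default 1). The sampling rate defaults to
600 Hz so one code bit is exactly 10 samples and a 4-bit lag is exactly 40
samples; circular trial shifting is then sample-exact, which makes the
zero-noise oracle tests exact (at 1000 Hz a 4-bit lag is 66.67 samples and
shifts are rounded to the nearest sample with a warning).

Population structure has three axes, all chosen once as plausible for
occipital VEPs and then frozen:

* **Similarity clusters** (default 2): prototypes differ in kernel peak
  latency (~45 ms spread), rebound strength, and — decisively — scalp
  topography, rotated within a two-profile subspace (~60° spread at
  `cluster_separation = 1`). Topography differences are genuine
  signal-geometry differences that whitening cannot and should not remove;
  they are what makes cross-cluster transfer harmful rather than merely
  unhelpful, the structure subject selection exploits.
* **Channel shift** (`shift_strength`): the symmetric transform is exactly
  the family that whitening-based alignment removes — a rotation component
  would survive whitening — so TL-LEDA-ASS versus TL-ASS is a clean
  parameter-recovery contrast. At `shift_strength = 0` all subjects share
  the channel frame and alignment is immaterial, which the tests assert.
* **Subject quality** (`snr_range`, amplitude SNR of the unit-RMS source
  signal against channel noise, default 0.08–0.15): chosen so the
  subject-specific baseline at 5 training trials per class sits in the 0.5–
  0.7 range rather than at ceiling, the regime where transfer learning is
  worth having.

What the generator does **not** emulate: structured (1/f, alpha) background
EEG, eye/muscle artifacts, within-session nonstationarity, multi-dipole
responses, or realistic forward head models. Passing tests therefore show
that the pipeline recovers the structure this model generates — code-locked
templates under linear channel shifts and cluster-structured similarity —
not that it attains any particular accuracy on real recordings.

## Problem sizes used by the test suite

Unit and property tests run on a reduced geometry (15-bit code, 4 targets,
3-bit lags, 3 channels at 300 Hz) where every covariance is 15 × 15 and a
full LOSO run takes well under a second. The end-to-end acceptance checks
use the full 16-target geometry: a noiseless 4-subject population for the
perfect-decoding and label-shuffle checks, and ten seeds of a clustered
8-subject population at 5 training trials per class for the algorithm
ordering (TL-LEDA-TSS ≥ TL-LEDA-ASS ≥ TL-ASS and TL-LEDA-ASS > SSL on mean
LOSO accuracy). Ten seeds of eight subjects keep the full comparison near
ten minutes on one core; the ordering is stable well before that.

## Known limitations

* The super-covariance dimension grows as `Nc(Z+1)`; beyond ~16 targets or
  many channels the eigendecompositions dominate run time (channel selection
  would be the natural remedy and is out of scope).
* The affine-invariant MDM route stores full covariances and uses the
  fixed-point mean; it is provided for comparison, not tuned for speed.
* Unsupervised alignment of test data is a batch operation over the whole
  test set, matching offline evaluation; no incremental/online variant is
  provided.
* The TSS inner criterion is an accuracy on shifted training data; when it
  saturates (very clean data), the smallest-`c` tie rule makes the selection
  conservative by design.
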