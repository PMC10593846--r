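---
title: "Methods: transient spectral network states with tdehmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transient spectral network states with tdehmm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tdehmm)
```

This vignette is the package's own account of its methods: the generative
model and its assumptions, the parameters that matter and why their defaults
are what they are, the numerical choices, and what the synthetic-data tests do
and do not establish about real recordings.

## The problem

Multichannel electrophysiological recordings (here: parcellated source-space
MEG/EEG, 42 cortical regions at 250 Hz in the motivating application) are
modelled as the alternating activation of a small number of hidden network
states. Each state is a large-scale functional network with a characteristic
frequency content and spatial power distribution; states wax and wane on a
50–300 ms timescale. The package infers the states, their per-sample posterior
probabilities, and their temporal, spectral and spatial profiles, at the group
level, from the concatenated recordings of all subjects.

## Preparation: leakage correction, embedding, PCA

**Symmetric leakage orthogonalization.** Source-reconstructed parcel time
series suffer zero-lag signal leakage from volume conduction. We demean each
region and replace the data matrix by its closest (Frobenius-norm) matrix with
mutually orthogonal rows — the orthonormal polar factor `U V'` of the SVD —
rescaled to the original row norms. Demeaning first guarantees the output rows
are both orthogonal and zero-mean, hence exactly uncorrelated at lag zero. The
construction treats all regions symmetrically (no reference region) and
commutes with region permutation; it fails loudly on rank-deficient input,
naming the deficient dimension, because "closest orthogonal matrix" is then
not unique.

**Time-delay embedding.** Lags −7…+7 (15 copies; 60 ms at 250 Hz) stack
delayed copies of every region, so that a Gaussian observation model on the
embedded vector captures lagged cross-correlations — i.e. band-limited power
and phase-coupling — without the parameter explosion of an autoregressive
observation model. The `max(|lag|)` samples at each edge, where some lag is
unavailable, are dropped rather than padded; an index map records the
surviving original sample indices so event timing stays exact downstream (an
error of max-lag samples, 28 ms, would visibly shift evoked latencies).

**PCA.** The embedded features (regions × lags) are reduced to *P* = 2 ×
regions principal components, fit on the concatenation across subjects so the
basis — and therefore the state definitions — is shared at the group level.
Each subject's regions are z-scored beforehand so no subject or region
dominates the shared basis. The low component count relative to the embedding
dimension biases the model toward slower rhythms, which is intended: the
long-range synchronization phenomena of interest live below ~25 Hz. Scores are
*not* whitened by default (`standardizeScores = FALSE`): state identity lives
in the covariance structure of the scores, and whitening would flatten exactly
the directions the states are defined by. The flag exists because the
convention varies between toolboxes.

## The variational Gaussian HMM

States follow a Markov chain with transition matrix *A* and emit
*y_t | z_t = k* ~ N(μ_k, Σ_k). By default μ_k ≡ 0: embedded, standardized data
are zero-mean per feature, and fixing the means concentrates all state
identity in Σ_k, the usual convention for time-delay embedded HMMs
(`freeMeans = TRUE` switches to a Normal–inverse-Wishart treatment).

Priors are weak and conjugate:

- each row of *A*: symmetric Dirichlet, concentration 1;
- initial distribution: symmetric Dirichlet, concentration 1;
- Σ_k: inverse-Wishart with ν₀ = P + 2 (the smallest dof giving a finite
  mean) and scale matrix S₀ = diag of the pooled data variances, i.e. one
  pseudo-observation shaped like the data's diagonal.

The E-step runs exact forward–backward smoothing (compiled, with per-sample
scaling; log-space emission computation through Cholesky factors) on the
*expected log* parameters, per subject segment; the M-step applies the
closed-form conjugate updates. The reported free energy is the negative
evidence lower bound, −(log normalizer − KL of the variational posteriors
from their priors), evaluated once per cycle at matched points of the
coordinate ascent; it is mathematically non-increasing across full-batch
iterations, and the test suite asserts this to 1e-6. Convergence is declared
when the free-energy change falls below `tol` (default 1e-6 absolute);
hitting `maxIter` first raises a warning rather than failing silently.

Initialization is a Dirichlet-random responsibility matrix followed by an
M-step; `nRestarts = 5` independent restarts are run and the lowest final free
energy wins. This codifies the practice of running the model several times and
keeping consistent solutions. Two further numerical choices: returned point
covariances are the inverse-Wishart means plus `1e-6 × mean diagonal` jitter,
guaranteeing positive-definiteness for downstream Cholesky factorizations;
and Viterbi ties break toward the lower state index, for determinism.

A stochastic option (`minibatch = m`) updates the posterior from random
subject subsets with Robbins–Monro step sizes ((t + 2)^−0.7). It exists for
datasets too large for full-batch passes; it is an efficiency device, not part
of the model, and the free-energy monotonicity guarantee applies only to
full-batch runs.

**State matching across runs** (`alignStates`) maximizes, by exact assignment
for K ≤ 8, the summed Pearson correlation between vectorized matrix
logarithms of the state covariances — a log-Euclidean comparison that is
insensitive to overall scale and respects covariance geometry better than raw
element-wise correlation.

## Temporal characterisation

Posteriors are binarized by per-sample argmax (ties toward the lower index),
making fractional occupancy an exact partition of time — FO sums to one by
construction. Lifetimes are contiguous-visit durations, interval times the
gaps between visits of the same state, both reported in ms; visits never span
subject boundaries; a state never visited reports `NA`, not zero. A
`gammaThreshold` alternative exists (occupancies then need not partition
time), since binarization conventions differ across the literature.

Event-locked analysis epochs the state courses on [−200, 1200] ms around each
stimulus onset and subtracts the per-trial mean over [−200, −30] ms. The −30 ms
endpoint (not 0) keeps smoothing-induced pre-stimulus bleed of the evoked
response out of the baseline; edges round to the nearest sample (at 250 Hz
the epoch is 351 samples, the baseline 43). Onsets are mapped through the
embedding's index map, and trials with incomplete windows are dropped and
counted.

## The two-level GLM and permutation inference

First level (per subject): at every (state, timepoint), the trial-wise model
has a constant regressor plus one demeaned indicator per task condition
(six n-back conditions: 0/1/2-back × target/distractor). Demeaning makes the
constant the average response across conditions, which is how it is
interpreted; it also makes the six indicators sum exactly to the zero vector,
so the 7-column design is rank 6. We therefore solve by minimum-norm
pseudoinverse least squares: all condition-difference contrasts and the
constant are estimable, with unique least-squares values — the rank deficiency
affects only the arbitrary split of the grand mean, never a reported COPE.
Default contrasts: the mean, target−distractor at each load, and the three
load contrasts pooling targets and distractors.

Second level: the observed statistic is the across-subject mean COPE. The null
flips the sign of whole subjects at random — the natural exchangeability null
for mean-zero subject effects; whether the original analysis flipped signs or
permuted labels at the first level is not documented anywhere we could
follow, and sign-flipping is the standard group-level choice. Each permutation
records the maximum of |statistic| over all states and timepoints (per
contrast); a point is significant when its observed |statistic| reaches the
97.5th percentile of that max-null. This is a two-sided test at family-wise
α = 0.05, corrected across states and time by the max-statistic construction.
The test suite verifies, by Monte-Carlo over 100 null datasets at 250
permutations, that the family-wise false-positive rate lands in the 95%
binomial interval around 0.05, and that an injected occupancy boost of 3× the
trial-level SD over 200–400 ms is detected over at least half its window.

## Spectral characterisation

**State-weighted multitaper.** The aligned recording is cut into 2 s windows
with 50% overlap; each window's DPSS multitaper cross-spectrum (time-half-
bandwidth 4, 7 tapers — standard resolution choices for a 1–40 Hz band at
250 Hz; no parameter set is documented for the original analysis) contributes
to state k with weight equal to the window's mean posterior probability of k.
Windowed rather than per-sample weighting keeps each spectral estimate a
proper stationary-segment estimate; the cost is that state contrast builds up
statistically across windows, so short recordings give blurred state spectra
(the three-state benchmark uses 10⁵ samples ≈ 6.7 min for this reason).
Coherence is |S_ij|/√(S_ii S_jj), clipped to [0, 1] with unit diagonal; a
state with ~zero total weight yields `NA` spectra and a warning naming it.
The weighted estimates decompose consistently: the weight-averaged sum over
states equals the unweighted spectrum, which the tests assert to 1e-8.

**Frequency modes.** All (subject, state, region) PSDs and (subject, state,
pair) coherence spectra are stacked into one non-negative frequency × features
matrix and factorized jointly by multiplicative-update NNMF into M = 4
non-negative frequency profiles with non-negative loadings (best of 3 seeded
restarts; the residual trace is non-increasing by construction of the
updates). Joint factorization of PSD and coherence is the default reading of
"across nodes and connections"; `what = "psd"` / `"coherence"` factorize
separately. Modes are ordered by peak frequency and scaled to unit maximum.
The highest, low-gamma mode is computed like the others but flagged
`disregarded` in the returned metadata rather than silently dropped: the
PCA-reduced embedding under-represents high frequencies, so that mode is
untrustworthy by design.

**Maps and networks.** Mode-projected quantities are inner products of each
spectrum with the mode profile over frequency; group results average across
subjects; PSD maps are z-scored across regions per (state, mode). Projected
coherence connections are thresholded by a two-component univariate Gaussian
mixture (`mclust`, unequal variances): connections with posterior > 0.5 under
the higher-mean component are kept. Coherence projections are fitted raw (an
`arctanh` Fisher flag exists); a degenerate fit — collapsed variance or too
few distinct values — falls back to a 90th-percentile threshold with a
warning.

## The synthetic-data generator

The simulator produces what the analysis assumes: a sticky Markov chain
(diagonal `stickiness`, uniform off-diagonal mass — the single-parameter
family matching the ~70 ms lifetime / 4 ms sample regime; the default 0.945
gives 70 ms mean lifetimes at 250 Hz) over K states, each expressed as a
sinusoid at a state-specific center frequency shared by a region subset with
fixed pairwise phase lags and a fresh random phase per visit, plus white
noise (default SD 0.5 against unit amplitude — oscillation power about twice
the noise power on active regions, a strong but realistic rhythm). Sinusoids
rather than AR processes were chosen deliberately: they give exact spectral
ground truth for recovery tests. The event generator reproduces the blocked
n-back schedule (12 blocks × 20 stimuli, 4 blocks per load, 1 s stimulus +
1.8 s inter-trial, per-load target counts 25/23/28); the block order is a
seeded permutation, exposed rather than constrained, since no ordering rule
is documented. Event-locked modulation multiplies the per-sample probability
of a designated state inside a post-onset window and renormalizes, keeping
the path a valid inhomogeneous Markov chain. Blocks are generated
independently, so no trial straddles a block boundary.

What the simulator does **not** contain — and therefore what passing tests do
not establish about real data: no 1/f background spectrum, no measurement
leakage (signals are mixed only by the states themselves), no non-stationary
artifacts, no evoked waveforms beyond occupancy modulation, no sensor-space
physics. Recovery results on it validate the *implementation* (inference,
alignment, statistics, spectral estimation), not the neuroscientific validity
of any particular real-data decomposition.

## Problem sizes used by the tests and the acceptance script

The three-state benchmark runs at 10⁵ samples (≈ 6.7 min of 10-region data),
where the fit reaches ≈ 0.97 decoding accuracy, self-transitions within
±0.005 of truth and spectral peaks within one 0.5 Hz grid step; the recovery
trend test compares 5 × 10³ against 3 × 10⁴ samples over three seeds. GLM
calibration uses 100 Monte-Carlo datasets of 8 subjects × 24 trials at 250
sign-flip permutations. The end-to-end pipeline test runs three subjects of
70 s each with three states. These sizes were chosen as the smallest at which
the corresponding properties are stable, keeping the default suite fast
enough to run habitually.

## Known limitations

- Mutual exclusivity: exactly one state is active per sample; simultaneous
  network activations are outside the model class (mixture-of-states designs
  address this).
- The argmax binarization forces mean FO = 1/K; conventions that yield other
  averages (e.g. probability thresholds) are available via `gammaThreshold`
  but not the default.
- Windowed gamma weighting trades state specificity for spectral
  cleanliness; with lifetimes much shorter than the 2 s window, state spectra
  converge slowly in recording length.
- The number of states K is an input. Free energy comparisons across K are
  possible but no automatic selection rule is provided.
- NNMF solutions are non-unique up to scaling/permutation; mode ordering by
  peak frequency and restart selection by residual make runs reproducible,
  not canonical.
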