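---
title: "Information-theoretic metric learning for EEG intention decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-theoretic metric learning for EEG intention decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Self-paced movement experiments record continuous multichannel EEG while a
participant freely decides which of two keys to press. Decoding *which* key
was pressed — and, harder, which key is *about* to be pressed — from short
windows around the keypress is a standard binary brain–machine-interface
task. Plain classifiers answer "how accurately?", but a clinically useful
decoder should also answer "from which scalp locations?". This package
implements a pipeline that does both: supervised linear metric learning on
vectorized EEG trials, ν-SVM classification, and a per-channel *importance*
attribution of the learned projection.

## Matrix-based α-order entropy

All information measures are built from Gram matrices rather than density
estimates. For projected trials $y_i = A^\top x_i$, the Gaussian kernel
$\kappa_\sigma(y_i, y_j) = \exp(-\lVert y_i - y_j\rVert^2 / 2\sigma^2)$
yields $K_Y$; labels yield the binary same-class kernel $K_L$. The
α-order entropy of a PSD matrix $K$ with unit-trace normalization is

$$S_\alpha(K) = \frac{1}{1-\alpha}\,\log \sum_i \lambda_i^\alpha,$$

evaluated from the eigenvalues $\lambda_i$ of $K/\operatorname{tr}(K)$. The
joint entropy uses the Hadamard product $K_L \circ K_Y$ (PSD by the Schur
product theorem), and conditional entropy and mutual information follow by
the usual differences. We use natural logarithms throughout and $\alpha =
1.01$, which behaves like Shannon entropy. Two numerical choices matter:

* every Gram matrix — joint *and* marginal — is normalized to unit trace
  before the matrix power. Without this the marginal is unbounded and the
  conditional-entropy decomposition breaks;
* eigenvalues at or below `eig_clip` ($10^{-12}$) are dropped, in the
  entropy and in its gradient. For $\alpha > 1$ the derivative contribution
  of a structurally zero eigenvalue is exactly zero, so raising a clipped
  value to $\alpha - 1$ would be wrong, not merely inaccurate. Kernel
  entries below about $10^{-30}$ are flushed to exact zero: they carry no
  information and extreme magnitude ranges can destabilize LAPACK's
  `dsyevr` driver (for which an SVD fallback is also in place).

## The three learners

**CEML** minimizes $S_\alpha(L \mid A^\top X)$ subject to
$\operatorname{tr}(A^\top A) = p$. The constraint is enforced by rescaling
onto the trace sphere after every gradient step — the minimal retraction
that satisfies it exactly.

**EGML** maximizes the *entropy gap*
$E_\Pi[S_\alpha(L, Y_\Pi)] - S_\alpha(L, Y)$: the joint entropy under a
random permutation of the trial–label correspondence, minus the observed
joint entropy. The gap is near zero when the projection is tiny (all points
look identical to the kernel) and when it is huge (all points look
infinitely far apart), so it needs no trace constraint — the objective
itself penalizes bad scales. Two consequences shaped the implementation:

* the permutation set is drawn once per fit from the run seed and held
  fixed across iterations. A redrawn set would make the objective
  stochastic, breaking the line search and bit-reproducibility. Ten
  permutations is the default; the enumeration test at $n = 4$ pins the
  estimator against the exact 24-permutation average.
* initialization is scale-aware: the starting map is rescaled so the
  projected total variance equals $p\sigma^2$. Starting far from the kernel
  width would leave the optimizer on a flat plateau of the gap.

**NCA** maximizes the expected leave-one-out soft 1-nn accuracy
$\sum_i \sum_{j \in \mathrm{class}(i)} P_{ij}$ with
$P_{ij} = \operatorname{softmax}_j(-\lVert A^\top x_i - A^\top x_j\rVert^2)$
and $P_{ii} = 0$ (a point is never its own neighbor — required for the
leave-one-out reading). The softmax exponent is negative and the problem is
a maximization; both are the standard NCA conventions.

All three use full-batch gradient descent with Armijo backtracking
(c $= 10^{-4}$, shrink 0.5), at most 500 iterations by default, stopping at
a relative objective change below $10^{-6}$. Analytic gradients are checked
against central finite differences in the test suite. Default
initialization is the leading right-singular directions of the centered
data; a seeded random orthonormal start is available. The kernel scale for
CEML/EGML defaults to $\sigma = \sqrt{p/2}$, matched to PCA-conditioned
inputs whose total variance equals the dimension, so distances per
projected dimension are order one.

## Features and conditioning

Trials are 0.85 s windows (170 samples at 200 Hz) around each keypress
onset; the onset sample starts the movement window, making the pre-movement
window `[-0.85, 0)` and movement window `[0, 0.85)` disjoint. Three
vectorizations are provided:

* **F1B** — per channel, the real part of the DC bin plus (Re, Im) pairs of
  DFT bins 1–4 (≤ 4.71 Hz): 9 features × 21 channels = 189;
* **F1A** — bins 0–84 (Nyquist excluded): 169 × 21 = 3549;
* **F2** — the raw time series, channel-major: 170 × 21 = 3570.

The bin-counting convention (DC real-only, Nyquist dropped) is the unique
one producing both printed counts for a 170-sample window. PCA conditioning
mean-centers, keeps `d_pc` components, and applies one global scale so the
total variance of the transformed *training* data equals `d_pc`. PCA and
the metric learners are refit inside every cross-validation training
partition — never on validation or test folds.

## Classification and evaluation

Classification uses ν-SVM (linear or Gaussian kernel), delegated to the
LIBSVM solver; ν bounds the margin-error and support-vector fractions, and
is infeasible above twice the minority-class fraction — infeasible grid
cells are skipped and logged. Evaluation is a nested, stratified, seeded
10-fold cross-validation: every (d_pc, p, ν, σ_SVM) combination is scored
by an inner 10-fold CV on each outer training partition, the best inner
mean is refit on the full partition and scored once on the outer fold. Ties
break toward the simpler model (smallest d_pc, then p, then ν, then the
widest SVM kernel). Methods are compared by a two-sided paired t-test
across the ten matched fold accuracies; a zero-variance difference is
reported as a flagged degenerate case rather than an arbitrary p-value.

## Channel importance

The fitted composite map is $B = (Q s) A$, PCA loadings included, since
the attribution should speak about the original feature space. Distances in
the projected space are invariant to right-rotations of $B$, so columns are
first made identifiable through the SVD $B = UDV^\top$, keeping
$\tilde B = UD$ with singular values descending (each left singular
vector's largest entry is made positive so maps reproduce run to run). The
importance of channel $k$ in dimension $j$ is the fraction of column $j$'s
squared norm carried by that channel's rows; the overall importance is the
uniform mean over the $p$ columns. A zero singular value makes the ratio
0/0; such columns get the uniform value $1/N_{ch}$ and are flagged.
Topographic export interpolates channel values with inverse-distance
weighting on an approximate 2-D 10/20 layout — a display convention, not a
source model.

## The synthetic generator

`generate_recording()` emulates one self-paced session: by default 700
onsets with 2.5 ± 0.5 s uniform jitter, balanced classes, white plus 1/f
background noise (1 µV each), and additive effect templates — a negative
raised-cosine drift over the 170 pre-onset samples on F3/F4/Fz (the
readiness-potential analogue) and a raised-cosine bump over the post-onset
samples on C3/C4 (the motor response analogue), both 3 µV peak and both
class-lateralized: left-hemisphere and midline weights are
$(1 + s\,\mathrm{lat})$ and right-hemisphere $(1 - s\,\mathrm{lat})$ with
$s = \pm 1$ by class and lateralization 0.5, plus a class-signed slow wave
at half amplitude on the same channels. Templates are deterministic
waveforms rather than filtered noise so the planted structure is
analytically known and recovery is testable.

One consequence matters for attribution studies: every planted component is
an additive mean shift, and for a binary task all mean-shift components
collapse into the single discriminative direction $\mu_1 - \mu_2$ — the
Bayes-relevant subspace of an equal-covariance two-class problem is
one-dimensional. The learners reflect this faithfully: at $p > 1$ the
trailing projection dimensions carry (near-zero but nonzero) noise
directions, and because the overall importance averages the $p$ columns
uniformly, those dimensions dilute the map. End-to-end recovery experiments
therefore fit $p = 1$, which matches the planted structure; at $p = 3$ the
class-bearing dimension still concentrates on the planted channels (70–85 %
of its squared weight), but the two noise columns get equal votes in the
overall average. This is a property of the uniform column average applied
to binary tasks, not of the learners. The generator does *not*
emulate eye-blink or muscle artifacts, volume-conduction correlations
between channels, inter-subject variability, or session drift — so passing
recovery tests demonstrate correctness of the pipeline, not expected
performance on real recordings. Amplitudes and latencies are
order-of-magnitude plausible rather than calibrated to any dataset.

Sessions round-trip through a MAT v5 subset reader/writer matching the
public session-file layout (a struct with `data`, `marker`, `sampFreq`,
`chnames`); the reader also handles zlib-compressed elements and restores
channel order by name.

## Problem sizes and reproducibility

The test suite and the acceptance script run deliberately scaled-down
instances — sessions of 40–200 trials, grids of a few hyperparameter
combinations, optimizer budgets of 15–150 iterations, 3–5 permutations —
chosen so the full pipeline, including nested CV for all four learners,
completes on a single CPU in minutes while still exercising every stage at
meaningful sizes. Generator defaults keep the full session scale (700
trials). Every stochastic step (fold assignment, initialization,
permutations, the generator) derives from explicit seeds, and same-seed
reruns are bit-identical end to end.

## Known limitations

* Full-batch gradient descent is adequate at a few hundred trials per fold
  but cubic eigendecompositions make CEML/EGML expensive beyond ~1000
  trials; a stochastic or low-rank variant is out of scope.
* The entropy-gap expectation uses a fixed finite permutation sample; its
  variance shrinks slowly in the number of permutations.
* The paired t-test across folds inherits the usual caveat that fold
  accuracies are not independent; it is reported as a descriptive
  comparison, matching standard practice.
* Real session files exist in several MAT dialects; only the v5 subset
  described above is supported, and reading files written by other tools
  has been verified against the scipy writer, not against MATLAB itself.
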