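# egml — information-theoretic metric learning for EEG intention decoding

`egml` is an R package for decoding binary movement intention ("which key
is being — or about to be — pressed") from multichannel EEG, and for
attributing the decoder's decisions back to scalp channels. It is aimed at
BCI/neural-engineering researchers who want interpretable linear projections
rather than black-box classifiers.

## What it implements

**Matrix-based Rényi α-order entropy.** For trials projected by a linear map
A, a Gaussian Gram matrix K_Y and a binary label kernel K_L give

    S_α(K) = 1/(1−α) · log Σ_i λ_i^α,     λ_i = eigenvalues of K / tr(K),

with joint entropy via the Hadamard product K_L ∘ K_Y, and conditional
entropy / mutual information as the usual differences (α = 1.01 throughout).

**Three supervised linear metric learners** over vectorized EEG trials:

* **CEML** — minimize S_α(L | AᵀX) subject to tr(AᵀA) = p;
* **EGML** — maximize the *entropy gap*
  E_Π[S_α(L, Y_Π)] − S_α(L, Y), a permutation-calibrated mutual-information
  surrogate that self-limits the scale of A and needs no trace constraint;
* **NCA** — maximize the soft leave-one-out 1-nn accuracy
  Σ_i Σ_{j∈class(i)} P_ij with softmax P over negative squared projected
  distances.

**A full evaluation pipeline:** 0.85 s epochs around keypress onsets
([−0.85, 0) and [0, 0.85), 170 samples at 200 Hz); Cartesian Fourier
features (189-dim 0–5 Hz "F1B", 3549-dim full-band "F1A") and raw
time-domain vectorization (3570-dim "F2"); PCA conditioning with
total-variance normalization; ν-SVM (linear / Gaussian) under nested,
stratified 10-fold cross-validation; paired t-tests across matched folds.

**Channel importance.** The composite map B = (Q·s)·A is made identifiable
by SVD sorting (B̃ = UD, singular values descending); the importance of
channel k in projected dimension j is the fraction of column j's squared
norm on that channel's rows, averaged over dimensions for the overall map,
with CSV and topographic PNG export on the 10/20 montage.

**Synthetic sessions and file I/O.** A seeded generator plants
readiness-potential-like class structure (frontal pre-onset drift, C3/C4
post-onset deflection, class-dependent lateralization) in white + 1/f
noise, and recordings round-trip through a MAT v5-subset reader/writer
matching the public FreeForm session layout.

## Worked example

```r
library(egml)

rec <- generate_recording(synth_config(n_trials = 120, seed = 1))
ep  <- extract_windows(rec, "move")
fm  <- fourier_cartesian(ep, "0to5")      # 120 x 189

pca <- pca_condition_fit(fm, 20)
Z   <- pca_condition_apply(fm, pca)
pr  <- egml_fit(Z, ep$labels, p = 1, ocfg = optimizer_config(seed = 1))

imp <- channel_importance(sort_projection(compose_projection(pca, pr)),
                          attr(fm, "channel_index_map"))
round(sort(imp$overall, decreasing = TRUE)[1:4], 3)

cv <- nested_cv(fm, ep$labels, "egml",
                hyper_grid("F1B", d_pc = 20, p = 3, nu = c(0.2, 0.5)),
                "linear", seed = 1, ocfg = optimizer_config(max_iter = 15))
cv
```

Output:

```
#>    C3    C4    P4    A2
#> 0.427 0.337 0.062 0.032
#> <cv_result egml/linear: accuracy 1.000 +/- 0.000 over 10 folds>
```

The importance map puts ~76 % of its mass on C3/C4 — exactly the two
channels where the generator planted the post-onset class difference — and
the nested cross-validation decodes this clearly separable synthetic
session perfectly. On label-shuffled data the same pipeline drops to
chance (~0.5).

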