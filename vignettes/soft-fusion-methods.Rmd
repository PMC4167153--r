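---
title: "Methods: soft fusion of multichannel experts for leukocoria detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soft fusion of multichannel experts for leukocoria detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leukofuse)
```

## The problem and the model

Leukocoria — a white pupillary reflex visible in flash photographs — is the
most common presenting sign of retinoblastoma and of several other ocular
pathologies. `leukofuse` classifies a cropped eye image (the square region
bounded by the iris) as *leukocoric* (+1) or *healthy* (−1) by fusing a bank
of 27 per-channel expert classifiers with a Sugeno fuzzy integral.

The pipeline, per color channel $c \in \{R, G, B\}$:

1. **Illumination correction.** The channel image $I$ is transformed with the
   orthonormal 2-D DCT-II, the coefficients at $(0,0)$, $(0,1)$ and $(1,0)$
   are set to zero, and the image is inverse-transformed. Those three
   coefficients carry the constant offset and the lowest horizontal/vertical
   variation, so the corrected image $\hat I$ is exactly invariant to
   additive illumination offsets and approximately invariant to linear
   illumination ramps.
2. **Resampling** to a common $32 \times 32$ working resolution.
3. **Z-scoring** against a per-pixel mean and standard-deviation image
   estimated from the *training* images only.
4. **Karhunen–Loève projection** onto the two leading eigenvectors of the
   training covariance of the flattened images, giving a feature
   $x \in \mathbb{R}^2$.

Each channel's nine experts — three feed-forward neural networks, LDA, QDA
and four soft-margin SVMs (linear, quadratic, cubic polynomial, RBF) — are
trained on these 2-D features and expose a *certainty* $h(y_i) \in [0,1]$
for each class, with $h_{+} + h_{-} = 1$.

**Fusion.** Each expert $y_i$ carries a density $g^i \in (0,1)$, its
importance. The $g_\lambda$-fuzzy measure extends the densities to
coalitions through
$g(A \cup B) = g(A) + g(B) + \lambda\, g(A)\, g(B)$,
where $\lambda > -1$ is the unique root of
$\lambda + 1 = \prod_i (1 + \lambda g^i)$.
Sorting the experts by descending certainty and writing $A_i$ for the top-$i$
coalition, the Sugeno fuzzy integral

$$ e \;=\; \max_i \; \min\bigl(h(y_i),\, g(A_i)\bigr) $$

is the fused confidence that the evidence supports the class. The integral
is computed once with the positive certainties and once with their
complements; the larger integral wins, ties going to +1 (in a screening
context a false negative is costlier than a false positive).

**Densities from ranks.** Each expert is ranked per channel on 16
performance metrics (RMSE, NRMSE, $|\mu_\varepsilon|$, $\sigma_\varepsilon$,
ACC, TPR, FPR, SPC, PPV, NPV, FDR, MCC, F1, BER, AUC, Cohen's $\kappa$)
estimated by repeated stratified 10-fold cross-validation; rank 1 is the
value closest to the metric's target (0 for error-style metrics, 1 for
agreement-style ones), ties receive fractional ranks. With $r_i$ the average
rank of expert $i$ over the 16 metrics, the densities are the normalized
reciprocal ranks

$$ g^i = \frac{1/r_i}{\sum_j 1/r_j}, $$

which sum to one by construction and are anti-monotone in rank. The
normalization is deliberately by the sum of *reciprocal* ranks: dividing by
the sum of the ranks themselves would not give a unit sum, and a unit sum is
the property the density construction is meant to guarantee. Because the
densities sum to one, the fuzzy measure is additive and $\lambda = 0$; the
$\lambda$ machinery stays fully general for user-supplied densities.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `side` | 32 | working resolution after resampling (pixels) |
| `eps` | 1e-8 | floor for the per-pixel standard deviation in z-scoring |
| `K`, `repetitions` | 10, 10 | cross-validation folds and repeats (the full protocol uses 100 repeats; `repetitions = 100` reproduces it at ~10× the cost) |
| `stratified` | TRUE | keep the 37.5% positive share in every fold |
| `mode` | `"paper"` | density estimation mode (below) |
| `alpha` | 0.05 | significance level of the Nemenyi test |

Expert hyperparameters (hidden sizes 2/20/50, 3/10/15, 2/3/5 per channel;
SVM kernels and $C$, $p$, $\tau$ per channel) are fixed constants of the
published bank and are not searched.

## The synthetic data generator

The original 144-image photographic database is private, so the package
ships a generator that emulates its *statistical structure*: 54 leukocoric
and 90 healthy eyes (37.5% positive), square crops uniform between 19 and
138 pixels, uncontrolled illumination, varied iris colors and gaze angles.
Each image is a concentric-disc eye: sclera, iris annulus (iris radius
$0.48\,s$; HSV hue $\sim U[0.02, 0.65]$, value $\sim U[0.10, 0.95]$), and a
pupil disc (radius $U[0.25, 0.40]$ of the iris radius) displaced by gaze
jitter of up to a quarter iris radius. A healthy pupil is dark with a faint
red tint plus a small specular dot (radius $\min(2\text{ px},
0.45\,r_\text{pupil})$ — capped relative to the pupil so that at the 19-px
scale the dot cannot fill the pupil and invert the class contrast); a
leukocoric pupil is bright, low-saturation white/yellow (brightness
$U[0.66, 0.95]$). Illumination is an additive offset $U[-0.60, 0.60]$ plus a
linear ramp of up to 1.5 intensity units across the crop in a random
direction, followed by i.i.d. Gaussian noise (sd 0.45) and clipping to
$[0,1]$.

The illumination and noise levels were chosen once so that, under the
default conditions, the individual experts score in the 0.65–0.90 accuracy
band that the original study reports for its bank — the one quantitative
anchor available, since the paper gives no numeric description of its
illumination variation. Two consequences of the disc model are worth
stating plainly:

* separability is driven by pupil-versus-surround contrast, so with noise
  and illumination disabled the two classes are perfectly separated by mean
  pupil luminance (a property the tests exploit as a generator-level
  oracle);
* the *relative* difficulty of the color channels does not match real
  photographs — here the blue channel is hardest and red easiest, whereas
  photographic red reflexes make the red channel the noisiest. Passing
  benchmarks on synthetic data therefore validates the pipeline's
  mechanics, not its clinical performance.

Reproducibility: one stream draws the dataset-level quantities (label order,
sizes), and every image has a private stream derived from the dataset seed
and the image index, so any image can be regenerated independently of
generation order. Pixels are kept as doubles in $[0,1]$ in memory; 8-bit
quantization happens only when writing PNG.

## Numerical choices

* **DCT scaling.** The transform pair is orthonormal with
  dimension-appropriate scaling ($\sqrt{1/M}$, $\sqrt{2/M}$ along rows,
  $\sqrt{1/N}$, $\sqrt{2/N}$ along columns), so the inverse is exact for
  rectangular images and Parseval energy is preserved. Implemented as basis
  matrix products ($D_M X D_N^\top$), which is exact and fast at these sizes.
* **Resampling.** Separable weight matrices: exact area averaging when
  downsampling (anti-aliasing), linear interpolation between pixel centers
  when upsampling. Every weight row sums to one, so constant images are
  preserved exactly and a $32 \times 32$ input passes through unchanged.
* **KLT.** SVD-based (via `prcomp`), eigenvector signs fixed so the
  largest-magnitude entry is positive, and projections whitened by
  $1/\sqrt{\text{eigenvalue}}$. Whitening makes the feature scale
  commensurate with the published SVM kernel widths ($\tau = 0.5$–$2$);
  without it the raw projections of z-scored $32\times32$ images have scale
  10–30 and an RBF kernel at those widths degenerates to a majority-class
  predictor. LDA and QDA are invariant to this scaling.
* **$\lambda$ root-finding.** $\lambda = 0$ always solves the measure
  polynomial, so the solver works on $q(\lambda) = f(\lambda)/\lambda$
  (with $q(0) = \sum g^i - 1$ by continuity), bracketing the unique nonzero
  root in $(0, \infty)$ or $(-1, 0)$ according to the density sum, followed
  by Newton polishing; residuals are at machine precision even when
  $\sum g^i$ is within $10^{-6}$ of one. When $|\sum g^i - 1| < 10^{-9}$ the
  additive measure ($\lambda = 0$) is used directly.
* **Certainties.** ANN: softmax outputs (fit with `nnet`: single hidden
  layer, logistic hidden units, cross-entropy, BFGS, 300 iterations, seeded
  initialization — the original work does not state its training algorithm
  or activation, so these are documented defaults, not claims about it).
  LDA/QDA: Gaussian posteriors; a fold whose class covariance is singular
  falls back to a ridge-regularized ($10^{-6} I$) Gaussian fit. SVM: a
  unit-slope logistic of the signed decision value, oriented so positive
  favors +1 — deterministic and monotone, avoiding an inner Platt
  calibration the protocol never mentions.
* **Ties and degenerate cells.** Sorting ties in $h$ break by density, then
  position; equal integrals, tied votes and zero means all resolve to +1.
  Zero-denominator metric cells propagate as `NA` and are excluded from
  ranking with a warning, never coerced to 0. $\kappa$ is reported
  unclamped (it is negative for worse-than-chance prediction) even though
  the protocol tabulates its desired interval as $[0,1]$.
* **Nemenyi constant.** $q_\alpha$ is computed exactly as
  `qtukey(1 - alpha, k, Inf) / sqrt(2)` rather than from a printed table;
  for $k = 4$, $\alpha = 0.05$ this gives 2.5694 and
  $CD = 2.5694\sqrt{4 \cdot 5 / (6 \cdot 17)} = 1.1376$.

## Evaluation protocol and the two density modes

`run_repeated_cv()` repeats stratified 10-fold cross-validation; in every
fold the normalizer, the KLT bases and all experts are fitted from scratch
on the nine training folds. Per-fold metrics are averaged within each
repetition; AUC is computed rank-based on the scores pooled across a
repetition's test folds. The comparison of the four combiners (average,
weighted average, majority vote, soft fusion) uses $N = 17$ criteria: the 16
metric means plus the average across metrics of the per-repetition standard
deviation (statistical stability, smaller is better) — matching a
comparison over "17 performance metrics" with 16 metric rows plus a
variability row.

The original protocol estimates the densities from the same cross-validation
that later scores the combiners, which leaks test information into the
weights. Both readings are implemented: `mode = "paper"` reproduces the
faithful (leaky) protocol and is the default; `mode = "honest"` derives each
fold's densities from an inner cross-validation on that fold's training data
only, at roughly `inner_K` times the cost. Stratified folds are the default
because with 37.5% positives a plain random 14-point fold can lose a class
entirely; plain random folds remain available via `cv_config(stratified =
FALSE)`.

Desk-scale problem sizes: the examples, tests and the acceptance script run
10 repetitions of 10-fold CV on the 144-image default dataset (about half a
minute end to end); `repetitions = 100` reproduces the full protocol
unchanged.

## Model bundles

`save_model()` writes a directory with a JSON manifest (expert ids,
densities, $\lambda$, working resolution, z-scoring floor), per-channel
normalizer and KLT arrays as CSV, and the fitted expert objects as RDS
files. The RDS files are the one non-portable part: R's canonical fitted
models (`nnet`, `svm`, `lda`, `qda`) have no faithful array serialization
short of reimplementing their predict methods. Bundles are runtime
artifacts; nothing in the package source depends on them.

## Known limitations

* The synthetic benchmark validates mechanics, not clinical accuracy; none
  of the published photographic results are reproducible without the
  private database, and the package makes no attempt to match them.
* The fusion is flat over all 27 experts. A two-stage per-channel variant
  (fuse within channels, then across) is a plausible alternative reading of
  the architecture but is not implemented.
* Only binary classification and the Sugeno integral are supported — no
  Choquet integral, no multi-class extension.
* The ANN experts are the only stochastic component; they are seeded per
  expert and per fold, so all results are bit-reproducible for a given seed
  on a given BLAS.
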