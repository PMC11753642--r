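---
title: "Wrapper feature selection with Moth-Flame Optimization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrapper feature selection with Moth-Flame Optimization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mothflame)
```

## The problem

Automated classification of plant diseases from leaf and fruit images
typically runs deep feature extraction (one or more pretrained CNN
backbones), feature selection to discard redundant dimensions, fusion of
the surviving features across backbones, and a conventional supervised
classifier. The expensive, data-hungry part — training the backbones — is
deliberately outside this package: extraction is a pluggable contract, and
a deterministic block-statistics extractor stands in for it so the entire
downstream pipeline is testable at desk scale with synthetic data. What the
package *does* own is everything after the backbone: the Moth-Flame
Optimization (MFO) engine, the binary wrapper around it, serial fusion,
augmentation, the classifier presets and the metric suite.

## Moth-Flame Optimization

MFO is a population metaheuristic modeled on how moths navigate: a moth
holding a fixed angle to a distant light flies straight, but holding that
angle to a *nearby* light produces a logarithmic spiral into it. The
algorithm keeps two coupled sets:

* **Moths** — `N` search agents with positions $X_i \in [Lb, Ub]^D$,
  re-evaluated every iteration.
* **Flames** — an elitist archive: the best `N` positions among (previous
  flames, current moths), sorted ascending by objective value. Because the
  archive is a best-of-union, the best flame fitness is non-increasing in
  the iteration — elitism is structural, not incidental.

Each iteration every moth flies a spiral around a flame:

$$X_i(t+1) = D_i \, e^{bk} \cos(2\pi k) + F_j(t), \qquad
D_i = |F_j(t) - X_i(t)|$$

applied coordinate-wise, where $b$ is the spiral shape constant and
$k \in [a, 1]$ is drawn uniformly per moth *per dimension*, with
$a = -1 + t(-1/T)$ sliding from $-1$ to $-2$ over the run so late spirals
hug their flames more tightly. The flame a moth orbits is its own
rank-matched flame ($j = i$) while $i \le R$, and the $R$-th flame
otherwise, where the active flame count

$$R(t) = \operatorname{round}\!\left(N - t\,\frac{N-1}{T}\right)$$

shrinks linearly from $N$ to exactly 1 at $t = T$, collapsing exploration
onto the incumbent optimum. Implementation choices that the formulas do not
pin down, decided once and tested:

* **Rounding** of $R$ at halves is away from zero (base R `round()` is
  banker's rounding, which would break the published schedule examples).
* **Spiral constant** $b$ defaults to 1 and is exposed in `mfo_config()`.
* **Out-of-bounds repair** is coordinate-wise clamping to $[Lb, Ub]$ —
  the simplest contract that guarantees bounded positions; reflection was
  rejected as needlessly stateful.
* **Tie-breaks** in all fitness sorts are stable (first seen wins).
* **Objective direction** is minimization everywhere; callers maximizing a
  score pass its negation.
* **RNG contract**: one seeded stream per `mfo_optimize()` call;
  initialization draws moth-major (moth 1 dims 1..D, moth 2, ...), then
  each iteration draws one $k$ per moth per dimension in the same order.
  Identical `(objective, space, config)` triples are bit-reproducible.

The flame-count schedule above deserves one note: a literal reading of
some published statements of the algorithm makes the flame count a random
quantity, which would destroy the elitist memory that the flame
construction procedure assumes. This package implements the deterministic
shrinking schedule of the original algorithm.

## The binary wrapper

Wrapper selection scores candidate feature subsets by the performance of a
real classifier, not by a filter statistic. The optimizer searches the
continuous cube $[0,1]^d$; a position becomes a mask by thresholding at
0.5 (strict), with an all-false mask repaired to the argmax coordinate so
the search space stays closed. The objective is the standard
error-plus-size compromise:

$$\text{fitness}(m) = \alpha \cdot \text{cvError}(m)
  + (1-\alpha)\,\frac{|m|}{d}, \qquad \alpha = 0.99$$

* **cvError** is the stratified 5-fold error of the inner classifier
  (default 1-nearest-neighbor: fast, parameter-free, and sensitive to
  noise dimensions, which is exactly what selection should punish)
  restricted to the masked columns.
* The **fold assignment is a pure function of the fitness seed**, so
  fitness is deterministic in `(mask, data, spec)` and repeated masks are
  memoized within a run. For the 1-NN default, per-feature squared
  differences are precomputed once ($n^2 \times d$), making each mask
  evaluation a single matrix–vector product.
* $\alpha = 0.99$ keeps the error term dominant; the size term only breaks
  near-ties toward smaller subsets. Any monotone combination is
  defensible, so both $\alpha$ and the inner classifier are configurable.

Default search budget is $N = 20$ moths for $T = 50$ iterations (1000
evaluations). On 10-feature problems this is routinely within 1% of — and
usually equal to — the global optimum found by exhaustive enumeration of
all 1023 masks (`exhaustive_selection()`, the built-in oracle, refuses
$d > 15$).

## Serial fusion

Fusion is plain array concatenation: the fused table is the columns of
vector 1 followed by the columns of vector 2, values untouched, width
$d_1 + d_2$. The failure mode that matters in practice is silent row
misalignment between feature tables produced by different extractors, so
alignment is enforced (row counts always; sample ids row-by-row when an id
column is present, naming the first offending row) and every fused column
carries provenance (source table, original index/name), making the fusion
auditable and exactly invertible (`unfuse_features()`). No rescaling
happens at fusion time; heterogeneous-scale backbones can opt into a
per-column standardizer, which is off by default because plain serial
fusion does not rescale.

## Augmentation and the toy extractor

The three label-preserving transforms are 90° rotation
(counter-clockwise — the direction is a free choice since classification
is direction-invariant; it is fixed and documented), vertical flip and
horizontal flip. `augment_images()` emits original + 3 transforms per
image per repeat, so counts scale by exactly $4\times$ per repeat and the
class histogram scales uniformly; a compose mode re-augments previous
outputs ($4^g$) for larger targets. There is no randomness anywhere in
this module.

The built-in extractor partitions an RGB image into a $g \times g$ grid
and emits per-block, per-channel mean and standard deviation:
$2 \cdot 3 \cdot g^2$ features in $[0, 255]$ (96 at the default $g = 4$).
Remainder pixels on non-divisible dimensions are absorbed by the last
block row/column. It is a pure function of the pixels, so extraction is
bit-reproducible, and it has a useful testable symmetry: a horizontal flip
permutes the block features.

## Classifier presets and metrics

The registry implements the ten preset families common in point-and-click
ML toolboxes — cubic-, quadratic- and medium-Gaussian-kernel SVMs, linear
discriminant, a subspace-discriminant ensemble (30 LDA learners on random
half-dimension subspaces, posteriors averaged), kernel naive Bayes
(per-class per-feature kernel densities), and fine / weighted / cosine /
cubic KNN ($k$ = 1, 10, 10, 10). The abbreviations these presets travel
under are expanded inconsistently across the applied literature (Q-SVM as
"quantum" vs quadratic, KNB as "KNN Bayes" vs kernel naive Bayes, ...);
the registry documents the semantics it implements and every
hyperparameter is overridable.

The evaluation protocol reports **two clearly separated surfaces**: k-fold
cross-validation on the 80% training partition, and the held-out 20%
scored by a model fitted on the full training partition. Published
protocol descriptions often conflate "10-fold cross-validation" with "an
80:20 ratio"; reporting both, labeled, avoids ever mixing them. Metrics
are one-vs-rest per class in percent — recall, precision, F1, FNR, FPR —
plus unweighted macro averages and overall accuracy. Exact identities
(recall + FNR = 100; accuracy = 100·trace/total; F1 between min and max of
precision and recall) are asserted in the tests. Zero-denominator metrics
are reported as `NA` with a count of undefined entries, never coerced to
0, so tiny folds cannot silently inflate macro averages. Multiclass AUC is
deliberately not computed.

## Synthetic data: what it emulates and what it does not

`synthetic_features()` plants `d_informative` columns whose class means
sit at regular-simplex vertices scaled so every pair of class means is
exactly `separation` within-class standard deviations apart (requiring
`d_informative >= k_classes` keeps the construction exact), among
`d_noise` standard-normal columns; column order is permuted and the true
indices returned. `synthetic_images()` draws one lesion per image — a
class-specific (shape, color) signature among disc, ring and streak — at a
seeded random position on a uniform leaf-green background with Gaussian
pixel noise clipped to [0, 255].

These generators give every stage a ground-truthed input, but they are
deliberately simple: features are Gaussian with equal spherical
covariance, images have a single lesion, no lighting or pose variation, no
background clutter, no class imbalance. Passing tests therefore
demonstrate the *mechanics* — selection finds planted structure, fusion
preserves information, presets separate separable classes — not
performance on real field imagery.

## Problem sizes and observed behavior

The test and acceptance workloads were sized for a laptop-class single
core: sphere convergence uses $d=5$, $N=30$, $T=500$ over 10 seeds
(best fitness reliably below $10^{-2}$, typically $10^{-40}$ or better);
oracle comparisons use $d=10$ with 180 samples; recovery uses 5
informative + 45 noise features, 3 classes, 60 samples/class; the
end-to-end pipeline uses 160 synthetic images with extractor grids 3 and
5 over 5 seeds.

One empirical caveat worth stating honestly: at separation $2\sigma$ the
recovery task is near the edge of what the wrapper objective can express.
Per-seed recovery of the 5 planted features ranges 60–100% with a median
of 80% across 30 seeds, and masks that *beat* the true informative mask on
fitness sometimes include noise columns in its place — the inner 5-fold
1-NN error genuinely rewards them on that draw. More optimization budget
lowers fitness without raising recovery, which is the signature of an
objective-level, not optimizer-level, limit. At larger separations
recovery saturates quickly.

## Known limitations

* Image I/O supports PNG trees (plus in-memory arrays from any source);
  other formats should be decoded upstream.
* The KNN, kernel-naive-Bayes and subspace-discriminant predictors are
  exact but not engineered for very large $n$ (dense distance matrices).
* No multi-objective selection, no filter methods, no constraint handling
  beyond box bounds, no hyperparameter search in the presets.
* `evaluate_classifier()`'s wall-time field is informational and
  machine-dependent; it is never compared in tests.
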