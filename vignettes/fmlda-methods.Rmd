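---
title: "Fuzzy maximum-uncertainty discriminant analysis for NIR spectra: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy maximum-uncertainty discriminant analysis for NIR spectra: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmlda)
```

## The problem

NIR absorbance spectra are wide: a single scan over 10,000–4000 cm⁻¹ at
instrument resolution yields on the order of 1500 correlated channels,
while a grading study may have only a few hundred samples. Classical
LDA needs the inverse of the within-class scatter $S_w$, which has rank
at most $n - c$ and is therefore singular whenever $d > n - c$ — the
small-sample-size problem. The package implements three extractors that
remain well-defined in that regime, and the surrounding pipeline
(preprocessing, splitting, KNN, grid search) needed to use them.

## Models

### Scatter matrices

With class means $\bar{x}_i$, counts $n_i$ and global mean $\bar{x}$:

$$S_w = \sum_{i=1}^{c}\sum_{x_k \in c_i}(x_k-\bar{x}_i)(x_k-\bar{x}_i)^T,
\qquad
S_b = \sum_{i=1}^{c} n_i(\bar{x}_i-\bar{x})(\bar{x}_i-\bar{x})^T.$$

### Maximum-uncertainty shrinkage (MLDA)

The pooled scatter $S_p = S_w/(n-c)$ is eigendecomposed,
$S_p = \phi\Lambda\phi^T$, and every eigenvalue below the average
eigenvalue $\bar\lambda = \operatorname{tr}(S_p)/d$ is raised to
$\bar\lambda$ — including the $d-\mathrm{rank}(S_w)$ exact zeros of the
null space, which both enter the average and are replaced by it. The
rebuilt $S_w^* = \phi\Lambda^*\phi^T(n-c)$ is positive definite, and
the projection is the top $t \le c-1$ eigenvectors of $S_w^{*-1}S_b$.
The underlying assumption is that the small and null eigenvalues of the
pooled covariance are the least reliably estimated, so flooring them at
the average adds the least-informative (maximum-entropy) correction
rather than discarding directions as a PCA pre-step would.

### Fuzzy extension (FMLDA)

Fuzzy c-means replaces the crisp class means with centers that respond
to samples near class boundaries:

$$u_{ij} = \Big(\sum_{k=1}^{c}
  \big(\lVert x_j - v_i\rVert / \lVert x_j - v_k\rVert\big)^{2/(m-1)}
  \Big)^{-1},
\qquad
v_i = \frac{\sum_j u_{ij}^m x_j}{\sum_j u_{ij}^m},$$

iterated from the labelled class means until the largest per-center
displacement drops below $\varepsilon$ or `max_iter` is reached. The
fuzzy scatter pair is then built **around those centers with crisp
class assignment of the samples**,

$$S_{fw} = \sum_i \sum_{x_k \in c_i} (x_k - v_i)(x_k - v_i)^T, \qquad
S_{fb} = \sum_i n_i (v_i - \bar{x})(v_i - \bar{x})^T,$$

and treated exactly as in MLDA. Two deliberate interpretive choices:

* **Literal center-based sums.** Parts of the fuzzy-LDA literature
  weight each outer product by $u_{ij}^m$; this package implements the
  plain center-based sums above, where fuzziness enters only through
  the centers. With centers pinned at the class means the fuzzy fit
  reduces *exactly* to MLDA — a reduction the test suite asserts — which
  would not hold for the weighted variant. The weighted form is noted
  here but intentionally not built.
* **Class–cluster correspondence.** FCM is initialised at the per-class
  means of the labelled training data, so cluster $i$ stays matched to
  class $i$ and $S_{fb}$'s pairing of $v_i$ with $n_i$ is meaningful.
  FCM runs on the training rows only: the fitted transform must not see
  test data.

### Direct LDA (DLDA)

DLDA works in the range space of $S_b$: find $Y$ with
$Y^T S_b Y = D_b$ (descending) and $Y^T Y = I$, let
$Z = Y D_b^{-1/2}$, eigendecompose $Z^T S_w Z = U D_w U^T$, and take
$W = (D_w^{-1/2} U^T Z^T)^T$. $W$ diagonalizes $S_b$ and $S_w$
simultaneously. When fewer components are requested than
$\mathrm{rank}(S_b)$, the components with the *smallest* within-class
eigenvalues $D_w$ are kept — the standard direct-LDA preference for
directions where classes are tight; the choice is otherwise
unconstrained and is recorded here as this package's convention.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `fuzzifier` m | 2 (grid 1.1–5.0 by 0.1) | membership softness; $m \to 1$ crisp, large $m$ uniform. The grid starts at 1.1 because the exponent $2/(m-1)$ is undefined at $m = 1$. |
| `epsilon` | $10^{-5}$ | FCM stop threshold on the max per-center Euclidean displacement (absorbance units). |
| `max_iter` | 100 | FCM iteration cap; hitting it is reported as a message, not an error. `max_iter = 0` evaluates memberships at pinned centers. |
| `ncomp` t | $c-1$ | discriminant vectors; bounded by $c-1$ (MLDA/FMLDA) or $\mathrm{rank}(S_b)$ (DLDA). |
| `k` | grid 1, 3, 5, 7, 9 | KNN neighbourhood; odd values avoid most vote ties. |
| `train_fraction` | 0.7 | per-class train share; per-class count is `round(fraction × class size)`, so 6 × 60 at 0.7 gives exactly 252/108. |

SNV uses the sample ($n-1$) standard deviation denominator, the common
chemometric convention (configurable); the transform is idempotent and
invariant to per-row affine changes, which is precisely why it removes
the generator's multiplicative scatter exactly in the noise-free limit.

## Numerical choices

* The $S_w^{*-1}S_b$ eigenproblem is solved by symmetric whitening —
  factorize $S_w^*$, whiten $S_b$, solve a symmetric eigenproblem in
  the $c$-dimensional span of the center deviations, map back — never
  by forming the non-symmetric product. This is mathematically
  identical and numerically stable.
* For $d > n$ the eigenbasis of $S_w$ comes from the $n \times n$ Gram
  matrix of center-deviation rows; null-space eigenvalues are handled
  implicitly (they all shrink to $\bar\lambda$), so no $d \times d$
  matrix is ever formed. The dense route is kept for small $d$ and the
  two are cross-checked against each other in the tests.
* Gram/between-scatter eigenvalues are treated as zero below
  $10^{-10}$ of the largest; DLDA's $D_w$ is floored at $10^{-12}$
  before the inverse square root.
* Eigenvector sign is fixed by making the largest-magnitude entry of
  each column positive; MLDA/FMLDA columns are unit-normalized, DLDA
  columns keep the $D_w^{-1/2}$ scaling its formula prescribes.
* FCM's membership singularity (a point coinciding with ≥ 1 center)
  assigns $1/\#\text{coinciding}$ to those centers and 0 elsewhere.
* KNN ties are deterministic: equal distances resolve by training
  index, tied votes resolve to the class of the nearest neighbour
  among the tied classes.
* Degenerate inputs: a single class yields a zero $S_b$ with a warning
  (scatter) or an error (fits); constant rows are an error in SNV,
  naming the sample; `n ≤ c` is an error in the shrinkage.

## The synthetic generator

Real graded NIR data of the kind this pipeline targets are rarely
public, so the package ships a generator whose defaults emulate a
6-grade tea study: 6 classes × 60 samples × 1557 channels spanning
10,000 → 4000 cm⁻¹ (descending, as instruments scan), a dominant
absorption band at 7200 cm⁻¹ inside the 7300–7100 cm⁻¹ O–H/N–H
overtone region, and an extra-noisy window at 5500–5100 cm⁻¹. Each
sample is

$$x = a \cdot \big(\text{baseline} + \textstyle\sum_p
\text{amp}_{p,\text{class}}\, e^{-(w - \text{center}_p)^2 / 2\sigma_p^2}\big)
+ \text{noise},$$

with log-uniform per-sample scatter $a \in [0.8, 1.25]$, additive noise
of sd 0.005 AU (plus 0.015 AU in the noisy window) — magnitudes typical
of bench FT-NIR absorbance work — and class identity carried by ±5%,
∓4% and alternating ±3% amplitude offsets on three bands, so grades are
ordered but not collinear. Offsets of a few percent against ±20%
scatter make raw classes overlap strongly (the first-PC class ranges
intersect) while SNV-corrected classes are separable: exactly the
regime scatter-correction-plus-discriminant pipelines exist for.

What the generator does **not** emulate: instrument line shapes,
wavelength-correlated (pink) noise, water-vapour interference bands,
chemically realistic band assignments, and batch effects. Passing tests
on this caricature therefore demonstrate the algebra and the pipeline
plumbing, not field performance on real tea spectra.

The frozen test fixture uses the same recipe at 200 channels (seed
20230126), where the full default grid — 5 k-values × 40 m-values for
FMLDA plus 5 cells each for DLDA/MLDA, all on one shared 252/108
split — runs in seconds; test fits elsewhere use 40–200 channels. On
that fixture all three methods reach perfect held-out accuracy at
their best grid cell, and the FMLDA accuracy at a fixed middling
(m = 2, k = 1) cell varies between roughly 0.90 and 1.00 across
generator seeds: large m over-smooths the FCM centers toward the global
mean, so on harder realizations crisper fuzzifiers win — which is why m
is grid-searched rather than fixed.

## Known limitations

* The fuzzy scatter definition is the literal center-based one (see
  above); membership-weighted variants are out of scope.
* A single hold-out split per seed, as in the grading-study protocol
  the driver mirrors; no cross-validation.
* No JCAMP-DX/SPC readers — input is the package's wide CSV dialect.
* KNN is exhaustive-search; fine for hundreds of projected samples,
  not tuned for very large reference sets.
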