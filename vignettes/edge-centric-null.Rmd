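---
title: "Edge-centric functional connectivity under a static Gaussian null"
author: "edgenull"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-centric functional connectivity under a static Gaussian null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgenull)
```

## The model

Edge-centric analysis unwraps the node functional-connectivity (nFC)
matrix of a parcellated BOLD recording into per-frame contributions.
Given the z-scored signals $z_i(t)$ of $N$ parcels over $T$ frames, the
edge time series of the pair $(i,j)$ is the element-wise product
$c_{ij}(t) = z_i(t)\,z_j(t)$, whose time average is the correlation
$r_{ij}$. Three derived measures are in common use:

* the **edge FC** (eFC), the $E \times E$ matrix
  ($E = N(N-1)/2$) of normalised inner products between all pairs of
  edge time series;
* the **RSS**, the per-frame Euclidean norm of the edge-time-series
  vector, which peaks at frames of simultaneous large cofluctuation;
* **binary edge series**, the signs of the cofluctuations.

The central question this package operationalises: which features of
these measures carry information beyond the static nFC? The null model
answering it is the *static Gaussian null*: frames drawn i.i.d. from
$\mathcal N(0, \mathbf R)$, with $\mathbf R$ equal to the observed nFC.
This null preserves all spatial correlations and destroys all temporal
ones. Every measure above then has a closed form in terms of
$\mathbf R$ alone:

* $\mathrm{eFC}_{jk,lm} = \dfrac{r_{jk} r_{lm} + r_{jl} r_{km} + r_{jm}
  r_{kl}}{\sqrt{1 + 2r_{jk}^2}\sqrt{1 + 2r_{lm}^2}}$ (Isserlis / Wick
  factorisation of the Gaussian fourth moment) — `predict_efc()`;
* the all-pairs RSS is exactly $\lVert z(t)\rVert^2$, and
  $\mathrm{RSS}/\sqrt2$ is a generalised $\chi^2$: a sum of $N$
  independent $\Gamma(1/2,\ \sqrt2\,\lambda_i)$ components, one per
  eigenvalue $\lambda_i$ of $\mathbf R$ — `null_rss_distribution()`;
* the binarised edge $(j,k)$ is Bernoulli with
  $p_{jk} = \tfrac12 + \arcsin(r_{jk})/\pi$ (the orthant / arcsine law)
  — `bernoulli_probability()`;
* the expected frame given seed activity $z^*_k$ is
  $z^*_k\,\mathbf R_{\cdot k}$, the scaled seed column — the foundational
  coactivation-pattern (CAP) property — `caps_expected_frame()`.

Because the mixture mean is $\sum_i \lambda_i/\sqrt2 = N/\sqrt2$ while
the variance $\sum_i \lambda_i^2$ concentrates on the leading
eigenvalues, modular correlation structure (large blocks, hence large
$\lambda_1$) produces a heavy — indeed subexponential — RSS tail: large
cofluctuation "events" are *expected* under the null, and the frames
carrying them align with the leading nFC eigenvectors
(`alignment_profile()`, `rank1_fc()`). The spectral bound
$\mathrm{RSS}_{\mathrm{all}}/\sqrt2 \le \lambda_{\max}\lVert
w(t)\rVert^2/\sqrt2$ (with $w = \mathbf R^{-1/2} z$ the whitened frame)
is attained exactly on frames proportional to $u_1$.

## What the surrogate generator emulates — and what it does not

`sample_bold()` realises the null exactly: i.i.d. frames coloured by the
symmetric square root $\mathbf R^{1/2} = U \Lambda^{1/2} U^\top$ (not a
Cholesky factor, so whitening round-trips bit-for-bit with the spectral
module). The `ar1` variant scales innovations by $\sqrt{1-a^2}$ so the
*stationary spatial covariance is still* $\mathbf R$; it isolates
temporal autocorrelation as the only departure from the null.

The generator does **not** emulate haemodynamics, scanner noise,
motion, non-Gaussian amplitude distributions, or non-stationarity.
Passing tests therefore demonstrate the internal consistency of the
analytic predictions under their own assumptions — exactly the claim the
null model makes — not that real BOLD data satisfy those assumptions.
Default study conditions used across the test suite mirror a typical
resting-state regime: $T = 1200$ frames for event-reconstruction
checks, modular correlation models with within-module correlation 0.5,
and Monte-Carlo sizes of $10^5$–$10^6$ where a sampling tolerance is
asserted.

## Parameters that matter

* `rho_within`, `rho_between`, `module_sizes` (dimensionless
  correlations / node counts): control the planted eigenvalue spectrum;
  a uniform block of size $m$ contributes a leading eigenvalue
  $1 + (m-1)\rho$.
* `ar_coefficient` $a \in (-1,1)$: lag-1 autocorrelation of the AR(1)
  contrast.
* RSS `convention`: `"upper_triangular"` is the published definition
  $\sqrt{\sum_{i<j} c_{ij}^2}$; `"all_pairs"` is the exact identity
  $\lVert z\rVert^2$. The Gamma-mixture null is calibrated for the
  upper-triangular series through the norm approximation
  $\mathrm{RSS} \approx \lVert z\rVert^2/\sqrt2$, whose relative error
  is the fourth-moment ratio reported by `kurtosis_ratio()` (about
  $3/N$ for Gaussian data — negligible at $N = 200$, noticeable below
  $N \approx 20$).
* `k` (edge communities): defaults to 10, the conventional choice;
  exposed everywhere.
* z-scoring uses the population denominator ($T$), while correlation
  estimators use $1/(T-1)$; under this pairing the plain time mean of an
  edge time series equals the Pearson $r_{ij}$ exactly, which the tests
  exploit as an exact identity.

## Numerical choices

* **CDF evaluation.** The Gamma-mixture CDF is evaluated by an exact
  single-Gamma series expansion (a nonnegative mixture over the shape
  parameter on the smallest scale); truncation stops when the residual
  mixing mass drops below $10^{-9}$, which bounds the absolute CDF error
  by the same amount. Characteristic-function inversion (the Imhof-type
  oscillatory integral, adaptive quadrature, absolute tolerance about
  $10^{-6}$) is retained as `method = "imhof"`: it is the classic route
  and serves as an independent cross-check in the tests, but its
  integrand oscillates with frequency proportional to $x$, making it
  slow and fragile deep in the tail, so the series is the default.
  Repeated evaluation (KS testing) uses a cached 4096-point monotone
  spline over the support up to the $1-10^{-11}$ Chernoff-bounded tail.
* **PSD repair.** Explicit correlation inputs with smallest eigenvalue
  in $(-10^{-8}, 0)$ are clipped to zero and rescaled to unit diagonal;
  anything more negative is rejected as genuinely invalid.
* **Eigen conventions.** Eigenvalues sorted descending; eigenvector
  signs fixed by making the largest-magnitude component positive (ties:
  lowest index). Eigenvalues below $10^{-10}$ are dropped from the
  Gamma mixture and treated as a null space by the whitening
  pseudo-inverse. Degenerate spectra (gap $< 10^{-10}$) are flagged:
  cosines against individual eigenvectors of a degenerate block are not
  unique.
* **Ties.** Frame sorts break ties by frame index; exact-zero
  cofluctuations binarise to 0 and are counted (`tie_count`), keeping
  Bernoulli bookkeeping honest; consensus labelling breaks modal ties
  by the lowest label.
* **k-means.** `stats::kmeans` on eFC rows with plus-plus-style
  seeding, best of 20 restarts by inertia, fully seeded. Label matching
  across runs solves the assignment problem exactly (Hungarian
  algorithm) rather than greedily, so agreement fractions do not depend
  on arbitrary label order.
* **Edge distances** are computed in correlation units (the
  $(T-1)^2$ inner-product scale is divided out): only relative
  distances matter for clustering, and this makes them independent of
  the recording length.

## Open design points, resolved

* The percentile-sweep CAP curve averages *z-scored* frames; the
  average over all frames is then exactly zero and its correlation with
  the seed map undefined. The sweep therefore reports `NA` for a bin
  whose running average is constant, and the documented "sharp drop" is
  tested on raw Gaussian frames (population-zero mean, sample mean
  nonzero), where the terminal drop is genuine rather than an artefact
  of exact cancellation.
* The conditional-covariance refinement of the CAP alignment (its
  sample-correlation version drops one frame, an $O(1/T)$ effect) is
  covered by testing proportionality of the conditional frame to the
  seed value, not the constant.
* Similarities between a frame's FC estimate and eigenvector FC
  estimates are Pearson correlations of upper triangles and hence
  scale-invariant: weighting the eigenvector estimate by $\lambda_i$ or
  not gives identical values; the $\lambda_i u_i u_i^\top$ form is used.
* The KS test of an observed RSS series evaluates the null CDF exactly
  and uses the asymptotic two-sided Kolmogorov p-value, appropriate at
  the $T \approx 1200$ regime of typical resting-state runs; below
  $T = 10$ a warning flags the asymptotics as unreliable.

## Known limitations

* The KS **p-value** assumes independent observations. Temporally
  autocorrelated data with the correct spatial covariance have exactly
  the null *marginal* RSS law — the KS distance still vanishes with $T$
  — but serial dependence inflates the statistic's sampling
  variability, so rejection rates exceed the nominal level under strong
  autocorrelation even though the marginal law is correct. The test
  suite checks the marginal-law convergence directly and treats the
  p-value as calibrated only for i.i.d.-like data.
* The upper-triangular RSS calibration degrades for small $N$ (the
  $3/N$ fourth-moment correction); `kurtosis_ratio()` should be
  consulted before testing parcellations below a few dozen nodes.
* Empirical eFC materialises an $E \times E$ matrix; at $N = 200$ that
  is $19900^2 \approx 4\times10^8$ entries (~3 GB). The analytic
  predictions (`predict_efc` on demand, `predicted_node_distance` for
  node-level structure) are the low-memory path.

## Problem sizes used by the shipped verification suite

Exact identities run on $N \le 10$, $T \le 60$; Monte-Carlo checks use
$n = 10^6$ draws for moments and the arcsine law, $10^5$ for
distribution-equivalence and probability-integral-transform checks;
type-I error calibration uses 500 replicates of $T = 1200$; the
event-reconstruction and community-recovery checks use modular models
with $N = 50$ and $N = 20$ nodes. These sizes were chosen so every
asserted tolerance is at least three standard errors wide under the
stated sampling law.
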