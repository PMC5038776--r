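---
title: "SCM-driven weighted image fusion: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SCM-driven weighted image fusion: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SCMFusion)
```

## The problem

Different medical imaging modalities are complementary: CT renders dense
structures (bone, calcifications) with high contrast while MR resolves
soft tissue. Pixel-level fusion of a co-registered CT/MR pair aims to
produce a single image that keeps the salient content of both sources
without introducing artifacts, washing out contrast, or blurring detail.
This package implements a fusion method driven by a spiking cortical
model (SCM) together with the six quality metrics commonly used to score
fused images, and a synthetic phantom generator so the whole pipeline is
testable without any external image archive.

## The spiking cortical model

The SCM is a single-layer, locally connected 2-D spiking network in
which each neuron corresponds to one pixel. Neuron $(i,j)$ keeps a leaky
internal activity $F_{i,j}$ fed by the normalized pixel intensity
$O_{i,j} \in [0,1]$ and by linking input from the pulses of its
neighbours, and fires a binary pulse $Y_{i,j}$ when the activity exceeds
a leaky dynamic threshold $\Theta_{i,j}$:

$$F[n] = f\,F[n-1] + O + O\,(W \star Y[n-1])$$
$$\Theta[n] = g\,\Theta[n-1] + h\,Y[n-1]$$
$$Y[n] = \mathbf{1}\{F[n] > \Theta[n-1]\}$$

with the linking weight between neurons at offset $(d_k,d_l)$ equal to
$1/(d_k^2+d_l^2)$ and no self-linking. Iterated $N_{max}$ times this
emits a temporal series of binary pulse images whose structure tracks
segments and edges of the input; the per-pixel sum of the series is the
*firing-mapping image* (FMI) $T$, a compact integer representation of
image structure.

Conventions this implementation fixes where the model's common
description is silent:

* **Initialization.** $F = \Theta = Y = 0$, so every neuron with
  positive stimulus fires at $n = 1$ — the near-full first-iteration
  activation conventional for SCM/PCNN implementations.
* **Update order.** The recursions are applied literally with their
  printed index lags: $\Theta[n]$ absorbs $Y[n-1]$, and $Y[n]$ compares
  $F[n]$ against $\Theta[n-1]$. Many SCM codes instead let the threshold
  absorb the pulse fired at the same step; that variant is available as
  `ScmParams(thetaUpdate = "current")` but is not the default, because
  the package treats the printed scheme as normative.
* **Linking locality.** The inverse-square weight formula is formally
  global; the implementation restricts it to a
  $(2r+1)\times(2r+1)$ window with default $r = 1$ (3×3), the standard
  practical choice — the $1/d^2$ weights decay fast and the model is
  explicitly about local stimuli.
* **Boundaries.** The linking correlation is zero-padded: neurons
  outside the lattice never fire, so border neurons simply receive less
  linking input. A consequence worth knowing: on a *uniform* stimulus
  the border trains can diverge from the interior after linking kicks
  in; the lattice symmetry of the dynamics is exact, translation
  invariance near the border is not.
* **Ties.** The firing inequality is strict; $F = \Theta$ does not fire.
* **Arithmetic.** Double precision throughout; pulses stored as
  integers. The linking sum accumulates its nine offset terms in a fixed
  row-major order so the vectorized dynamics are bit-for-bit identical
  to a per-pixel scalar loop (this is tested).

## The fusion rule and weight

Both sources $A$ and $B$ are driven through the SCM with one shared
parameter set. Three patch statistics (all on
$(2L_p+1)\times(2L_p+1)$ patches, default $L_p = 1$) build the fusion:

1. **Local energy** $E = \sum_{patch} T^2$ of each FMI. The source with
   the larger local energy at a pixel is the *dominant* source there.
2. **Entropy similarity.** For each pixel and iteration, the binary
   Shannon entropy $H = -P^1\log_2 P^1 - P^0\log_2 P^0$ of the patch of
   the pulse image ($P^1$ = fraction of ones). Stacked over iterations
   these form a feature vector $V$ per pixel; the similarity is
   $S^{En} = 1 - \lVert V^A - V^B\rVert_2 / C_{S1}$.
3. **WLD similarity.** The Weber local descriptor differential
   excitation of each FMI,
   $\xi = \arctan\big(\sum_{patch}(T_{neigh}-T_{centre}) / T_{centre}\big)$,
   a Weber-law-scaled Laplacian response confined to
   $(-\pi/2, \pi/2)$; the similarity is
   $S^{WLD} = 1 - |\xi^A - \xi^B| / C_{S2}$.

The fusion weight is the product $\omega = S^{En}\cdot S^{WLD}$, and the
fused intensity is the energy-gated convex combination

$$U = \begin{cases}
\omega I^A + (1-\omega) I^B & E^A > E^B\\
(1-\omega) I^A + \omega I^B & E^A \le E^B.
\end{cases}$$

With the default constants $C_{S1} = 3N_{max}$ and $C_{S2} = 5\pi$, the
entropy distance is at most $\sqrt{N_{max}}$ and the excitation gap is
below $\pi$, so every weight lies in $(0.74, 1]$: the dominant source
always contributes the majority share, and similar regions are blended
almost symmetrically while dissimilar ones approach winner-take-all.

Further conventions:

* **Patch borders.** All patch statistics (entropy, energy, excitation)
  use symmetric mirror padding, so border statistics stay in-range and
  homogeneous regions stay exactly homogeneous.
* **Zero-firing centres.** $T_{centre} = 0$ makes the Weber ratio
  undefined; the denominator is floored at $\epsilon = 10^{-6}$, which
  saturates $\xi$ toward $\pm\pi/2$ for nonzero responses and keeps the
  output inside the arctangent range.
* **WLD input scale.** $\xi$ is computed on the raw integer firing
  times, not the display-rescaled FMI; the ratio is invariant to
  positive rescaling wherever $T > 0$, so this choice only affects
  zero-firing pixels.
* **Intensity scale of the rule.** The convex combination runs on the
  original 8-bit intensities while the SCM consumes the normalized
  copy; the rule is linear in the intensities, so this is equivalent to
  fusing normalized values up to a global factor and avoids a rescaling
  round-trip. Output stays in floating point; quantization (round half
  away from zero, clip to $[0,255]$) happens only on save.
* **Ties.** $E^A = E^B$ is grouped with the second branch — source B
  receives the weight $\omega$ — exactly as the rule is stated; no
  randomization. Swapping the inputs therefore reproduces the fused
  image at every pixel where the energies differ, while tie pixels may
  legitimately change.
* **Similarity range.** Similarities are not clamped; with a
  user-supplied very small $C_{S1}$ a negative $S^{En}$ is possible and
  is passed through as-is.
* **Feature distance.** The plain Euclidean norm. Scale/translation
  invariant alternatives (cosine, Pearson) are deliberately out of
  scope.

## The six quality metrics

`metricReport()` scores a triple $(A, B, U)$:

* **$Q_M$** — mutual information: $MI(A,U) + MI(B,U)$ from 256-bin
  joint histograms, in bits. Non-integer fused values are quantized to
  the 8-bit lattice for binning.
* **$Q_E$** — edge preservation: Sobel gradients give per-pixel edge
  strength and orientation; relative strength and orientation agreement
  (orientation taken modulo $\pi$: an edge and its reverse are the same
  edge) pass through the classical sigmoids
  ($\Gamma_g = 0.9994, \kappa_g = -15, \sigma_g = 0.5$;
  $\Gamma_\alpha = 0.9879, \kappa_\alpha = -22, \sigma_\alpha = 0.8$)
  and are averaged with the source edge strengths as weights. Each
  sigmoid is normalized by its value at perfect preservation, so a
  fused image that preserves every edge exactly scores exactly 1 —
  with the raw sigmoids even a perfect transfer would cap near 0.975,
  which would make the metric's own fixed point unattainable. The
  sigmoid shapes, hence the ordering of any two fused results, are
  unchanged by this normalization.
* **$Q_S$** — SSIM-based index: over 8×8 sliding windows (stride 1),
  where the sources agree ($SSIM(A,B) \ge 0.75$) the window scores the
  salience-weighted combination
  $\lambda\,SSIM(A,U) + (1-\lambda)\,SSIM(B,U)$ with
  $\lambda = s(A)/(s(A)+s(B))$ the local-variance ratio
  ($\lambda = 0.5$ when both variances vanish); where they disagree it
  scores the better of the two. $Q_S$ is the mean over windows.
  Intensities are normalized to $[0,1]$ first so the stabilizers
  $C_1 = C_2 = 2\times10^{-6}$ act on the intended scale.
* **$Q_L$** — fusion quality index: the product of two
  saliency-weighted factors (images and their Sobel-magnitude edge
  images), each the $C(w)$-weighted mean of the $\lambda$-combination
  above with $C(w) = \max(s(A|w), s(B|w))$. The saliency weight is kept
  as the plain maximum of the two window variances — the form used in
  the fusion-quality-index literature — because an additive offset term
  sometimes quoted with it can drive weights negative, which a saliency
  cannot be. When every window is flat the weighted mean degrades to
  the plain mean.
* **$Q_T$** — fusion similarity metric: per window, universal image
  quality index (UIQI) scores $Q(A,U)$ and $Q(B,U)$ blended by the
  covariance ratio $sim = \sigma_{AU}/(\sigma_{AU}+\sigma_{BU})$
  clipped to $[0,1]$ ($0.5$ when both covariances vanish, keeping the
  metric symmetric under source exchange). UIQI's $0/0$ windows (both
  flat) score 1 when the windows agree and 0 otherwise.
* **$STD$** — sample standard deviation of the fused image
  (denominator $N-1$), a plain global contrast measure.

Window shape is a design point the metric literature leaves open; this
package uses overlapping 8×8 windows with stride 1 by default and
exposes both in the API and the CLI. All window metrics are implemented
with integral-image box sums and are tested against explicit per-window
loops at tolerance $10^{-8}$.

## The synthetic phantom generator

`makePair()` emulates the complementarity the method exploits, not the
physics of either modality. One seed fixes a shared anatomy layout — an
elliptical head with a rim band — from which both modalities are
rendered: the CT-like image is piecewise constant (background 5,
interior 40, bright ring 230 at normalized elliptic radius
$[0.88, 1]$, plus three sharp dense blobs at 200–255), while the
MR-like image ramps smoothly from background to a textured soft-tissue
interior (base 100, four Gaussian bumps of amplitude 25–60 and an
oriented sinusoid of amplitude 25), with independent Gaussian noise of
$\sigma = 2$ intensity units per modality. The pair is co-registered by
construction, and the salient gradients of the two modalities live in
disjoint regions (rim and blobs vs interior texture) — the property the
energy gate needs to have something to choose between.

What the phantoms do *not* model: MR bias fields and intensity
nonstandardness, CT Hounsfield calibration, partial-volume effects,
registration error, or anatomy more complex than blobs and texture.
Passing tests on phantoms therefore demonstrate the pipeline's
contracts (determinism, convexity, weight bounds, metric behaviour and
the superiority direction over naive averaging under complementary
salience), not clinical image quality.

The RNG is pinned (Mersenne–Twister, inversion normals) and the
generators restore the caller's RNG state, so all fixtures are
bit-reproducible across platforms from their seed alone.

## Problem sizes and runtime choices

The test suite runs the bit-for-bit SCM oracle on 16×16 stimuli
(20 seeds), the pipeline oracle on 16×16 pairs (10 seeds), window-metric
oracles on 32×32 triples, and the fusion-vs-averaging comparison on
twenty 128×128 phantom pairs; the acceptance script scores one 256×256
pair, the canonical slice size for this kind of data. These sizes keep
every check exhaustive at full parameter defaults while the whole suite
completes in well under a minute on one core.

## Known limitations

* Two sources only, single-channel, 8-bit; no color/multi-spectral
  (PET/SPECT) path and no registration — inputs are assumed
  co-registered and intensity-standardized.
* The energy tie-break is asymmetric by construction (ties go to the
  second source); on natural images ties are rare, on synthetic
  piecewise-constant inputs they are not.
* $N_{max}$ is fixed at 20 by default; the model family is known to be
  sensitive to iteration count (too few or too many iterations lose
  detail in the firing maps), and no per-image selection rule is
  implemented.
* The WLD component uses only differential excitation, not the full
  multi-orientation descriptor.
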