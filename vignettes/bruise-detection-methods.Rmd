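---
title: "Detecting early fruit bruises from hyperspectral cubes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting early fruit bruises from hyperspectral cubes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Early mechanical bruises in dark-skinned fruit such as blueberries are
nearly invisible to the eye: the skin pigments hide the color change, and
the tissue damage shows up mainly as a drop in near-infrared reflectance
(water loss from ruptured cells) and as a subtle change in the spatial
texture of the fruit surface. Near-infrared hyperspectral imaging captures
both at once: a cube with two spatial axes and one wavelength axis
(roughly 935–1720 nm for the line-scan instruments used in this setting),
where every pixel carries a full reflectance spectrum.

`hsibruise` implements the complete desk side of such a screening
pipeline: radiometric correction and region-of-interest extraction,
spectral and image feature extraction, spectral–image feature fusion,
classifier construction, and — the methodological core — a multi-strategy
improved beluga whale optimization (MSBWO) algorithm used to tune the SVM
hyperparameters. Because raw fruit cubes are rarely distributable, a
synthetic-scene generator reproduces the statistical structure the
pipeline assumes, so every stage is testable end to end.

## Preprocessing

**Flat-field correction.** Raw intensity is converted to relative
reflectance per pixel and band as

$$ I_c = \frac{I_R - I_D}{I_W - I_D} $$

with $I_R$ the captured cube, $I_W$ a white diffuse-reflector reference
and $I_D$ the dark-current reference. Pixels where white and dark
coincide (dead pixels) receive an epsilon denominator and are counted in
the cube metadata; corrected reflectance is clipped to $[0, 1.5]$ to
bound specular outliers, also with a reported count.

**Band trimming.** The extreme bands of the instrument range are noisy,
so analysis is restricted to the closed interval 950–1650 nm. On the
synthetic grid (below) this retains exactly 200 of 224 bands.

**Segmentation and cropping.** The fruit is separated from the dark
background by Otsu's histogram threshold (256 bins, via `EBImage`) on a
single band image — the band with maximal class contrast, near 1081 nm
for blueberry tissue; the mask band is configurable since the optimal
band is data dependent. Background pixels are zeroed and an 80 × 70 pixel
region of interest is cropped, centred on the mask centroid with zero
padding at the borders. The per-sample mean spectrum is the average of
masked pixels per band.

## Feature extraction

**Spectral features.** Either the full trimmed spectrum (200 bands) or a
subset chosen by the successive projections algorithm (SPA). SPA grows a
chain from each candidate starting band, at each step adding the band
with maximal column norm after orthogonal projection onto the complement
of the span of the already-selected columns — minimally collinear
forward selection. Each candidate subset is scored by the 5-fold
cross-validated RMSE of an ordinary least-squares fit of the numerically
coded labels (sound = 0, bruised = 1); the chosen size is the smallest
one whose RMSE is numerically indistinguishable from the global minimum
(a parsimony tie-break that matters when the response is perfectly
explained). `k_max` defaults to 40.

**Image features.** A 28-value texture descriptor from the gray-level
co-occurrence matrix (GLCM) of the mask-band ROI plane: the four
statistics

- contrast $\sum_{i,j} P_{ij} (i-j)^2$,
- energy $\sum_{i,j} P_{ij}^2$,
- entropy $\sum_{i,j} P_{ij}(-\ln P_{ij})$,
- homogeneity $\sum_{i,j} P_{ij} / (1 + (i-j)^2)$

in each of the four directions (0°, 45°, 90°, 135°), plus the mean,
population standard deviation and variance of each statistic across
directions. Quantization is uniform over the plane's `[min, max]` into 8
gray levels and the co-occurrence offset is 1 pixel — conventional
choices documented here because the descriptor definition does not fix
them. Counts are symmetrized (offset and its negation, the Haralick
convention) and normalized to relative frequencies.

**Fusion.** Spectral and image blocks are min–max scaled to $[0, 1]$
per feature using the *training rows only*, then concatenated spectral
first; full spectrum + GLCM gives 228 columns. Single-block categories
pass through the same training-row scaler so all categories enter the
classifiers on a common scale.

## Classifiers and metrics

Three conventional models: an RBF-kernel SVM (`e1071`), a random forest
(500 trees, $\sqrt p$ features per split), and PLS-DA (`mixOmics`;
components chosen by 5-fold CV up to 10, class by a 0.5 threshold on the
predicted score). Samples are split 7:3 stratified. Performance is the
quartet accuracy, precision, recall and F1 (harmonic mean of precision
and recall), with **bruised as the positive class** — screening aims to
catch bruises. Undefined metrics (zero denominators) are reported as
`NA` rather than silently zeroed.

The SVM baseline hyperparameters are $C = 1$ and
$g = 1/(p \cdot \mathrm{Var}(X))$, the common library default.

## The optimizers

### Classic beluga whale optimization

A population of $n$ candidate solutions ("whales") in a box. Each
iteration, whale $i$ draws $B_0 \sim U(0,1)$ and the balance factor
$B_f = B_0(1 - T/(2T_{max}))$ routes it to:

- **Exploration** ($B_f > 0.5$): paired-swimming update through a random
  dimension permutation, with $(1+r_1)\sin(2\pi r_2)$ modulation on even
  dimensions and the cosine form on odd ones, pulled towards a random
  partner whale.
- **Exploitation** ($B_f \le 0.5$): $X' = r_3 X_{best} - r_4 X_i +
  C_1 \cdot LF \cdot (X_r - X_i)$ with jump strength
  $C_1 = 2 r_4 (1 - T/T_{max})$ and a Mantegna Lévy step
  $LF = 0.05\,\mu\,\sigma_\mu / |\nu|^{1/\beta}$, $\mu,\nu \sim N(0,1)$,
  $\beta = 1.5$. The published form of the step is typographically
  garbled (it reuses one symbol for the normal draw and the scale
  constant); the Mantegna reading adopted here reproduces the
  conventional scale $\sigma_\mu(1.5) \approx 0.6966$. The scale constant
  uses a real signed root so it stays defined on the whole declared
  $\beta \in (1, 3]$ range.
- **Whale fall** ($B_f \le W_f$, with $W_f = 0.1 - 0.05\,T/T_{max}$):
  respawn $X' = r_5 X_i - r_6 X_r + r_7 X_{step}$ with step length
  $(ub - lb)\exp(-2 W_f n\, T/T_{max})$.

Every proposal is clamped to the bounds, evaluated, and accepted
greedily — kept only if it improves that whale's fitness. Greedy
acceptance is what guarantees the non-increasing convergence curve; the
published pseudocode says only "validate new positions", which leaves the
acceptance rule open, and greediness is the choice that makes the
monotonicity contract checkable. $B_0$ is redrawn per whale per
iteration because the pseudocode indexes the balance factor by $i$. The
exploration equation's dimension indexing is internally ambiguous in its
source; this implementation uses a fresh random permutation of
dimensions per whale per iteration, with the dimension's parity choosing
the sine or cosine form.

All random draws come from R's generator in a documented order (see
`?bwo`), so a run is exactly reproducible from its seed — the test suite
checks the full trajectory against an independently written
straight-line trace.

### Multi-strategy improvements

Four modifications, each independently switchable in
`msbwo_control()`:

1. **Good point set initialization.** Deterministic low-discrepancy
   seeding: with $p$ the smallest prime satisfying $(p-3)/2 \ge d$, the
   generator point is $r_k = \{2\cos(2\pi k/p)\}$ and point $i$ has
   coordinates $\{r_k \cdot i\}$ mapped onto the box. More even coverage
   than uniform draws (the suite checks its minimum pairwise distance
   beats the median of random seedings).
2. **Elite pool guidance.** The top three solutions plus their
   arithmetic mean form a pool; each exploitation step draws one member
   uniformly as its guide instead of always using the single best —
   "weighted average" is undefined in the source, so equal weights are
   used. With fewer than three whales the pool degrades to the available
   members.
3. **Adaptive Lévy / spiral fusion.** With probability `fusion_prob`
   (default 0.5 — the fusion rule itself is unspecified in the source,
   and a Bernoulli switch is the simplest symmetric reading) the whale
   takes an adaptive Lévy step $x' = x + \alpha(t)\,\mu\sigma_\mu /
   |\nu|^{1/\beta}$ with $\alpha(t) = \alpha_0 (1 - t/T)^\gamma$
   ($\alpha_0 = 0.1(ub - lb)$ per dimension, $\gamma = 2$); otherwise a
   whale-optimization spiral contraction towards the guide,
   $X' = X^* - A^* |C^* X^* - X|$ with $A^* = 2a^*r - a^*$, $C^* = 2r'$,
   and $a^*(t)$ decreasing 2 → 0. The default replaces the classic
   exploitation move wholesale with the drawn strategy, which is the
   reading that matches the stated control flow; a `"skeleton"` mode
   that keeps the $r_3/r_4$ skeleton and swaps only the Lévy term is
   provided since the source does not settle the point.
4. **Golden-sine population update.** After the whale-fall stage, in
   iterations where at least one whale fell (scope configurable to only
   the fallen whales), every whale gets a golden-sine proposal
   $V' = V|\sin r_1| - r_2 \sin(r_1)\,|x_1 D - x_2 V|$ with
   $r_1 \in [0, 2\pi]$, $r_2 \in [0, \pi]$, $D$ the incumbent best, and
   golden-section coefficients $x_1, x_2$ on $[-\pi, \pi]$
   ($\tau = (\sqrt5 - 1)/2$), accepted greedily. When the stage improves
   the global best the interval is shrunk by one standard golden-section
   step (and reset once it collapses below $10^{-8}$).

Setting `exploit = "classic"` and switching all three strategy flags off
makes `msbwo()` reproduce `bwo()` draw for draw — the suite asserts the
trajectories are identical, which pins down that the improvements are
exactly the four deltas above.

### SVM tuning

`tune_svm()` searches $(C, g)$ on a log10 scale inside
$C \in [0.01, 100]$, $g \in [0.001, 10]$, minimizing
$1 - \text{(5-fold stratified CV accuracy)}$ computed on the training
split only — the held-out test rows never enter the fitness, a
deliberate strengthening over protocols that leave this unstated. The
reference protocol is population 50, 100 iterations, and 30 independent
repeats whose per-run optima $(C, g)$ are averaged arithmetically before
a final refit; the repeats/population/iterations are free parameters
because desk-scale runs use smaller values (below).

## The synthetic scene generator

`scene_spec()` emulates what the pipeline assumes about real acquisition
sessions, with every default chosen once and documented here:

- **Wavelength grid:** 224 uniform bands starting at 935 nm with step
  $(1720 - 935)/224 \approx 3.50$ nm. This step is chosen so the
  950–1650 nm trim retains exactly 200 bands, the band count the
  preprocessing convention expects; a grid with both endpoints pinned at
  935 and 1720 would retain 199.
- **Spectra:** a smooth decreasing baseline (0.82 → 0.58) minus Gaussian
  absorption dips near 980, 1081, 1206 and 1280 nm (water and pigment
  features), times a per-fruit brightness factor
  $\sim N(1, 0.04)$, minus a class offset of 0.045 for bruised tissue,
  plus i.i.d. pixel noise (sd 0.03). Sound reflects more than bruised.
- **Texture:** Gaussian-filtered white noise modulates the spectrum
  multiplicatively inside an elliptical fruit region on a dark
  background; the correlation length is 5 px for sound and 4 px for
  bruised tissue with relative amplitude 0.05, deliberately only mildly
  separable — early bruises barely change the skin appearance, and image
  features are meant to be the weak modality.
- **Calibration:** the class offset and texture contrast were fixed in a
  single calibration pass targeting fused-feature SVM accuracy in the
  85–95 % regime with image-only features clearly weaker, and were not
  revisited afterwards. Scene-to-scene spread at 50 cubes per class is
  substantial (30-sample test sets quantize accuracy in 3.3-point
  steps), so individual seeds can land below that band; the ordering
  fused > image-only is what holds consistently. With the offset at 0
  and equal textures the pipeline sits at chance, the no-information
  control.

What the generator does **not** emulate: biochemical absorption physics,
bruise time evolution, multi-fruit scenes, instrument striping, or
specular highlights. Passing tests therefore demonstrate that the
pipeline's mechanics are correct and that its orderings (fusion beats
single modalities; tuning beats defaults) hold under the assumed
statistical structure — not that the specific accuracies transfer to any
real cultivar.

## Numerical choices and degenerate inputs

- Out-of-bounds positions are clamped to the nearest bound everywhere.
- A constant image cannot be thresholded (error); a constant feature on
  the training rows scales to 0 with a warning.
- `0 ln 0 := 0` in the GLCM entropy; a constant image has a single unit
  co-occurrence entry and descriptor (0, 1, 0, 1) per direction.
- SPA skips rank-deficient candidate subsets with a warning and stops a
  chain early when all residual norms fall below $10^{-12}$.
- Tuning repeats that fail are excluded from the mean with a warning;
  if all fail the tuner errors.
- Metric denominators of zero yield `NA`, never a silent 0 or 100.

## Problem sizes used by the checks

The test suite and the acceptance script run at desk scale, chosen as
the package's own testing conditions: optimizer benchmarks use $d = 2$,
$n = 30$–50, 200–300 iterations and 20 seeds; synthetic scenes use 50
cubes per class (the tuning comparison uses population 12, 12
iterations, 3 repeats); unit fixtures use coarse 24-band grids. The
reference tuning protocol (50/100/30) remains the default of
`tuning_protocol()`.

## Known limitations

- The exploration equation's mixed indexing follows one of several
  defensible readings of its source (documented above).
- PLS-DA component choice uses plain CV accuracy; no one-standard-error
  rule.
- SPA's phase-2 scoring refits OLS per (start, k) pair; for very wide
  matrices this is the dominant cost (`starts` can restrict candidates).
- The CLI is a thin wrapper (`inst/cli/hsibruise`) over the exported
  functions; it does not manage long-running experiment queues.
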