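---
title: "Hybrid clustering segmentation of brain tumors: methods and design"
author: "BrainTumorKFCM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid clustering segmentation of brain tumors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BrainTumorKFCM)
```

## The problem and the pipeline

Tumor and edema regions are hyperintense on FLAIR MR slices, but
intensity-based segmentation of them is fragile: Gaussian acquisition
noise moves pixels across class boundaries, the skull is as bright as
the lesion, and iterative clustering algorithms started from random
centroids can return visibly different segmentations on identical
input. `BrainTumorKFCM` addresses all three with a three-stage
pipeline on 2D grayscale slices normalized to $[0,1]$:

1. **Preprocessing** — adaptive Wiener denoising, then morphological
   skull stripping, leaving only brain parenchyma;
2. **Clustering** — fuzzy C-means with a Gaussian kernel distance,
   initialized deterministically by K-means++ (together: K⁺⁺GKFCM),
   partitioning in-brain intensities into $k = 4$ tissue classes
   (CSF, gray matter, white matter, tumor/edema);
3. **Extraction and postprocessing** — the cluster with the maximal
   centroid is taken as tumor (FLAIR-hyperintense), and the binary
   mask is repaired by hole filling and a binary median filter.

`runPipeline()` executes the whole chain; each stage is also an
exported function.

## The clustering model

Classical fuzzy C-means minimizes
$J_{\mathrm{FCM}} = \sum_{i=1}^{c}\sum_{j=1}^{N} u_{ij}^{\,n}\,(x_j - v_i)^2$
subject to $\sum_i u_{ij} = 1$, $0 \le u_{ij} \le 1$, where $x_j$ is
the $j$-th pixel intensity, $v_i$ the $i$-th centroid, $u_{ij}$ the
fuzzy membership and $n > 1$ the fuzzifier. The kernel variant
replaces the squared distance by a kernel-induced one,

$$J = 2\sum_{i=1}^{c}\sum_{j=1}^{N} u_{ij}^{\,n}\,\bigl(1 - K(x_j, v_i)\bigr),
\qquad K(x,y) = \exp\!\left(-\frac{(x-y)^2}{2\sigma^2}\right),$$

which saturates for far-away points: a noise outlier at distance
$\gg \sigma$ contributes a bounded $2u_{ij}^n$ instead of a quadratic
penalty, so centroids are far less dragged by tails. Alternating
updates minimize $J$:

* **membership** (exact constrained minimizer for fixed centroids)
  $$u_{ij} = \frac{(1 - K(x_j, v_i))^{-1/(n-1)}}
                  {\sum_{k=1}^{c} (1 - K(x_j, v_k))^{-1/(n-1)}};$$
* **centroid** (stationarity fixed point, kernel at the previous
  centroids)
  $$v_i = \frac{\sum_j u_{ij}^{\,n}\,K(x_j, v_i^{\mathrm{prev}})\,x_j}
               {\sum_j u_{ij}^{\,n}\,K(x_j, v_i^{\mathrm{prev}})}.$$

The centroid step is a majorize–minimize step: $1 - e^{-t}$ is concave
in $t = (x - v)^2$, so its tangent at the previous centroid is a
linear majorizer of the loss, and the kernel-weighted mean above is the
exact minimizer of that majorizer. Together with the exact membership
step this guarantees $J$ never increases, which the test suite asserts
at $10^{-12}$ relative tolerance rather than merely observing it.
Iteration stops when $|J^{(i)} - J^{(i-1)}| \le \varepsilon$; the first
element of `objectiveTrace()` is $J$ at the initial centroids, so a
very large $\varepsilon$ performs exactly one update iteration.

A membership update with the non-reciprocal form (without the
$-1/(n-1)$ exponent and the normalizing sum) cannot satisfy the
row-stochastic constraint, so the standard constrained-minimizer
update and its kernel analogue are used throughout.

### Deterministic K-means++ initialization

Instability of clustering under random initialization is the problem
the hybrid design targets, so only the *first* center involves the
seeded RNG, and it is drawn from the **sorted unique intensity
values** — by value, not by pixel position. Every subsequent center is
chosen deterministically as the value maximizing
$D(x)^2 / \sum_x D(x)^2$, with $D(x)$ the distance to the nearest
already-chosen center (the farthest-point rule; ties go to the
smallest value). The usual probabilistic $D^2$ sampling is
intentionally *not* used: with a fixed seed the whole pipeline is
reproducible bit for bit, and drawing by value-index makes the result
independent of pixel ordering. The K-means++ centers are refined by
Lloyd iterations before the fuzzy loop starts.

### Numerical conventions

* **Singularities.** A pixel exactly equal to a centroid has
  $1 - K = 0$; it receives crisp membership in that cluster (lowest
  index if several distances are exactly zero). Rows whose weights
  overflow to non-finite values fall back to the same crisp rule at
  the minimal distance.
* **Duplicate centroids** would make the update singular; exact
  duplicates produced by a degenerate fixed point are nudged apart by
  one ulp of the data range. K-means++ spreading makes this a
  safeguard rather than a code path seen in practice.
* **Permutation invariance.** All reductions (cluster means, weighted
  sums) run over value-sorted pixels and results are un-permuted
  afterwards, so the label map is bitwise independent of pixel order —
  floating-point addition is not associative, and without a canonical
  summation order boundary pixels could flip between runs on permuted
  input.
* **Label ties** in the hard label map go to the lowest cluster index.
* Clustering uses scalar intensity only, within the brain mask; no
  spatial features are appended.

### Parameters and defaults

| parameter | default | units / scale | rationale |
|---|---|---|---|
| `k` | 4 | classes | CSF, GM, WM, tumor/edema inside the brain |
| `fuzzyIndex` (n) | 2 | — | the standard FCM fuzzifier; $n \to 1$ approaches hard K-means |
| `sigma2` | 0.1 | squared $[0,1]$ intensity | kernel width ≈ the squared span of two tissue-class separations; large enough that in-class variation stays in the quasi-quadratic regime, small enough to damp outliers |
| `epsilon` | 1e-5 | objective units | $J$ on a 256×256 slice is $O(10^2)$; 1e-5 halts well past visual convergence |
| `maxIter` | 100 | iterations | fits converge in well under 30 iterations on all studied inputs |
| `wienerWindow` | 3 | px | smallest window with meaningful local statistics; preserves thin boundaries |
| `openRadius` | `NA` → `round(min(dim)/51)` | px | disk radius 5 at 256×256; must exceed skull-ring thickness and stay far below brain radius |
| `medianWindow` | 3 | px | removes isolated pixels without eating tumor boundary detail |
| `seed` | 1 | — | drives the noise draw and the first K-means++ pick |

With $\sigma^2 \to \infty$, $1 - K \approx (x-v)^2/2\sigma^2$ and the
constant factor cancels in the membership ratio, so GKFCM degenerates
to classical FCM; the suite checks agreement within $10^{-4}$ at
$\sigma^2 = 10^6$ against the independent `fcmFit()` implementation.
For that comparison both fits are run to their actual fixed points
(tolerance far below either objective's scale), because the kernel
objective is $\sim \sigma^2$ times smaller than the Euclidean one and
a shared absolute $\varepsilon$ would otherwise stop the kernel fit
prematurely.

## Preprocessing

**Adaptive Wiener filter** (local-statistics form): with local mean
$\mu$ and variance $s^2$ over the window, the output is
$\mu + \frac{\max(0,\, s^2 - \nu)}{\max(s^2, \nu)}(x - \mu)$, where
the noise variance $\nu$ defaults to the mean of the local variances.
Flat tissue collapses to its mean while edges ($s^2 \gg \nu$) pass
through almost unchanged.

**Skull stripping** is decided as: Otsu threshold on the denoised
slice → morphological opening with a disk → keep the largest
8-connected component → fill interior holes. The opening alone removes
the thin bright skull ring (thinner than the disk diameter); the
largest-component step discards any surviving non-brain fragments; hole
filling returns dark interior structures (ventricles) to the mask.
An explicit threshold can replace Otsu when the bimodal assumption
fails. An empty foreground raises a "no head detected" error rather
than returning an empty mask.

Morphological conventions: structuring elements are exact Euclidean
disks ($x^2 + y^2 \le r^2$) or squares, built in-package and shared
with the brute-force oracles in the tests; out-of-image pixels count
as background for erosion and dilation (masks are padded and cropped
around the EBImage primitives, which would otherwise replicate the
border); connectivity is 8 for foreground components, which EBImage's
4-connected labelling is extended to by merging diagonally touching
labels.

## Extraction, postprocessing, metrics

Tumor/edema is FLAIR-hyperintense, so the cluster with the maximal
centroid is extracted by default; an explicit intensity threshold
(`threshold` / `--tumor-threshold`) instead selects every cluster
whose centroid exceeds it. The mask is then repaired by hole filling
followed by a binary median (= majority) filter; the order mirrors the
repair logic: first restore interior pixels, then smooth the boundary
and delete speckle. The majority filter is not strictly idempotent —
shrinking a multi-pixel island can take a few passes — but on
tumor-shaped masks it stabilizes by the second application, which the
suite checks on such fixtures.

`segMetrics()` reports two metric families from the TP/TN/FP/FN pixel
tallies. The `paper` family keeps the formulas of the original method
description exactly as printed — Dice $= (TP+TN)/(TP+TN+FP+FN)$
(which is pixel accuracy), Sensitivity $= TP/(TP+FP)$ (precision),
Specificity $= FN/(TN+FN)$ — for comparability with results reported
under those definitions; the `standard` family gives the usual
Dice $= 2TP/(2TP+FP+FN)$, Sensitivity $= TP/(TP+FN)$,
Specificity $= TN/(TN+FP)$. Recall $= TP/(TP+FN)$ is identical in
both. Zero denominators yield `NaN` with a warning instead of an
error so cohort evaluation never aborts. Evaluation defaults to the
whole image; because background TN dominate, the `paper` Dice is
close to 1 almost regardless of tumor overlap — restrict with `roi`
(e.g. the brain mask) when that matters.

## The phantom generator

`generatePhantom()` supplies ground-truthed inputs with exactly the
structure the method assumes: a dark background (0.02), a bright
skull ring (0.75) of ~3 px at 256×256 (scaled with size), a 4-px dark
subarachnoid gap — CSF is attenuated on FLAIR, and the gap is what
makes the skull ring a separate component after thresholding — an
outer gray-matter band (0.45) over a white-matter interior (0.65),
two CSF ventricles (0.25), and one rotated-ellipse tumor (0.90,
semi-axes `tumorRadiusFrac * size` × 0.8 of that) placed by the seeded
RNG inside the white matter, clear of the ventricles and the brain
edge. Class separations are ≥ 0.2, i.e. several noise standard
deviations at the highest studied variance 0.02 (σ ≈ 0.14). Ellipse
boundaries are perturbed by seeded low-frequency cosine modes (small
on the brain outline, larger on the GM/WM border) so tissue borders
are not analytic ellipses. Zero noise gives exactly constant classes;
fixed seeds give bit-identical phantoms.

What the phantom deliberately does **not** emulate: bias fields /
intensity inhomogeneity, Rician (magnitude-MR) noise, partial-volume
voxels, within-tissue texture, anatomy beyond two ventricle blobs,
and multi-focal or ring-enhancing lesions. Passing the phantom suite
therefore demonstrates the pipeline's correctness and its noise
robustness under the stated model — clean class structure plus
additive Gaussian noise — not clinical-grade performance on real
FLAIR data, where the unmodelled effects above are often the dominant
difficulty.

## Study conditions exercised by the tests

The suite and `scripts/acceptance.R` run, among others: membership
normalization and objective monotonicity over 20 random 500-pixel
instances at $k=4$; the flat-kernel FCM limit on a 200-pixel instance
at $k=3$; ten repeated end-to-end runs on one 256×256 phantom
(byte-identical masks); noiseless-phantom recovery of the configured
class means within 0.02 and tumor Dice ≥ 0.99; the noise-robustness
protocol at variances {0.005, 0.01, 0.02} × five seeds (mean standard
Dice ≥ 0.90 per variance, spread ≤ 0.05); and the
postprocessing-benefit comparison on ten phantoms at variance 0.02.
These sizes are the package's chosen operating points for the
phantom experiments.

## Known limitations

* Strictly 2D and single-modality; no T1/T1c/T2 fusion, no DICOM.
* Tumor selection presumes a hyperintense lesion; on sequences where
  the lesion is not the brightest tissue class the maximal-centroid
  rule must be replaced by an explicit threshold.
* The skull-strip recipe expects a head-versus-background bimodal
  histogram; heavy bias fields would break the single Otsu threshold.
* Edema and tumor core are not separated (one hyperintense class).
* No component-size filtering beyond the median filter: a large bright
  false-positive region distant from the tumor would survive
  postprocessing.
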