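# BrainTumorKFCM

Segmentation of hyperintense tumor and edema regions in 2D FLAIR-like
brain MR slices, for image-analysis work that needs a reproducible,
noise-robust intensity-clustering pipeline rather than a trained
model. The package implements a hybrid method: adaptive Wiener
denoising and morphological skull stripping, **K-means++-initialized
Gaussian-kernel fuzzy C-means** (K⁺⁺GKFCM) clustering of brain
intensities into four tissue classes, threshold-based tumor
extraction, and morphological/median postprocessing — plus the
evaluation metrics and a ground-truthed synthetic brain-phantom
generator so everything is testable end to end without any external
image data.

## The method

Pixels inside the skull-stripped brain mask are soft-clustered by
minimizing the kernel objective

$$J \;=\; 2\sum_{i=1}^{c}\sum_{j=1}^{N} u_{ij}^{\,n}\,\bigl(1 - K(x_j, v_i)\bigr),
\qquad K(x,y)=\exp\!\Bigl(-\tfrac{(x-y)^2}{2\sigma^2}\Bigr),$$

subject to $\sum_i u_{ij}=1$, by alternating the closed-form
membership update
$u_{ij} \propto (1 - K(x_j,v_i))^{-1/(n-1)}$ and the kernel-weighted
centroid update
$v_i = \sum_j u_{ij}^n K(x_j,v_i) x_j \,/\, \sum_j u_{ij}^n K(x_j,v_i)$
until $|J^{(i)}-J^{(i-1)}|\le\varepsilon$. The bounded kernel distance
damps the influence of noise outliers, and initialization is a
*deterministic* K-means++ (farthest-point selection; only the first
center uses the seeded RNG), so a fixed seed reproduces the
segmentation bit for bit. The tumor is the cluster with the maximal
centroid (FLAIR-hyperintense), repaired by hole filling and a binary
median filter. See the vignette
(`vignettes/brain-tumor-segmentation.Rmd`) for the full model,
parameter rationale, and numerical conventions.

## Worked example

```r
library(BrainTumorKFCM)

ph  <- generatePhantom(size = 256, noiseVar = 0.01, seed = 42)
run <- runPipeline(grayImage(ph), segConfig(seed = 42),
                   truth = tumorMask(ph))
run
#> SegRun: tumor mask 2361 px, 6 GKFCM iterations, seed 42
#>   standard Dice vs truth: 0.9958

sort(centroids(run@clustering))
#> [1] 0.2587027 0.4533161 0.6495337 0.8933260

run@metrics
#> MetricsReport (rows: printed formulas / standard definitions)
#>            dice sensitivity specificity recall
#> paper    0.9997      0.9975      0.0002 0.9941
#> standard 0.9958      0.9941      0.9999 0.9941
```

The phantom has tissue classes at intensities {CSF 0.25, GM 0.45,
WM 0.65, tumor 0.90} under Gaussian noise of variance 0.01; the fitted
centroids recover those means to ~0.01 and the postprocessed tumor
mask overlaps the ground truth at standard Dice 0.9958. The metrics
table reports both families: the `paper` row uses the formulas of the
original method description as printed (its Dice is pixel accuracy,
its Specificity is FN/(TN+FN) — hence the small value at near-perfect
segmentation), the `standard` row the usual definitions.

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/segment.R phantom --size 256 --noise-var 0.01 --seed 42 --out-dir ph/
Rscript inst/scripts/segment.R segment ph/image.tif --truth ph/tumor_truth.png --out-dir seg/
Rscript inst/scripts/segment.R evaluate seg/tumor_mask.png ph/tumor_truth.png
```

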