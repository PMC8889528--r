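---
title: "Methods: rule-based and convolutional CTC identification on imFISH images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based and convolutional CTC identification on imFISH images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the calling rule

Circulating tumor cells (CTCs) are identified on immunofluorescence
in-situ hybridization (imFISH) micrographs with three co-registered
channels: DAPI (nuclear counterstain), CEP8 (chromosome-8 centromere
probe; one punctate signal per centromere copy, so more than two signals
indicates aneuploidy), and CD45 (pan-leukocyte antigen). The
interpretation criteria are applied per cell: aggregated or superposed
nuclei are eliminated before scoring; the remaining cells are CTCs exactly
when they are DAPI-positive, CD45-negative, and carry at least three CEP8
signal points. `ctcfish` implements this rule twice — once explicitly
(`call_cell()`) and once as a learned convolutional classifier
(`build_model()`/`train_cnn()`) — together with the segmentation that
produces per-cell crops and the evaluation protocol that scores both
callers under severe class imbalance.

## Synthetic data: what it emulates and what it does not

No public per-cell imFISH corpus with usable ground truth exists, so the
package ships a first-class simulator (`sim_params()`,
`generate_image()`, `generate_dataset()`). Its defaults define the study
conditions used throughout the tests:

* images of 256×256 px with 8 nuclei each; nuclei are filled ellipses
  with semi-major axis 11–16 px and axis ratio at most 1.5 (compact,
  round-ish nuclei);
* CEP8 spots are disks of radius 2 px placed inside the nucleus with
  pairwise separation above one spot diameter, so rendered spots are
  disjoint; spot counts are drawn from a distribution peaked at two
  signals (the diploid centromere count: weight 0.55) with a tail up to
  eight (aneuploidy); 10% of spots are placed straddling the nucleus
  boundary, emulating centromeres not fully inside the nucleus;
* CD45-positive cells (unconditional fraction 0.6, reflecting residual
  leukocytes after depletion) receive a uniform intensity lift over the
  nucleus footprint, so a mean-intensity test is sufficient but not
  trivially perfect;
* each image gets a multiplicative exposure gain drawn from 0.9–1.1 and
  additive Gaussian noise (SD 6 on the 8-bit scale), emulating
  exposure/enrichment noise;
* a configurable fraction of nuclei (default 5%) is placed overlapping a
  neighbor; non-overlapping nuclei keep at least 20 px boundary
  clearance so that genuinely distinct cells remain separable after the
  segmenter's smoothing and dilation steps.

`generate_dataset()` draws a per-cell CTC indicator at a requested
prevalence (0.049 in the imbalance experiments, matching a 694 : 13,472
class mix) and samples cell attributes conditional on that label, so the
ground-truth labels satisfy the calling rule exactly by construction. One
master seed expands into per-image substream seeds; identical parameters
and seed give bit-identical rasters and manifests.

The simulator deliberately omits optical realism: no point-spread
convolution, no chromatic aberration, no autofluorescence texture, no
debris or impurities other than Gaussian noise, and intensity
distributions are simpler and better separated than in stained patient
material. Passing the end-to-end benchmarks therefore demonstrates that
the pipeline's logic is correct and self-consistent on images with the
right geometry and failure modes — not that the fixed thresholds would
transfer to a given microscope without recalibration.

## Segmentation

`preprocess_dapi()` follows a fixed operator order on the DAPI channel:
grayscale (identity on a single channel) → Gaussian denoise → gradient
map → Gaussian denoise → binarize → averaging smooth → four erosions →
four dilations. Decisions taken where the procedure leaves freedom:

* **Gradient operator.** First-order Sobel derivatives. The default
  `gradient_mode = "magnitude"` uses |∂x| + |∂y|; the subtractive variant
  ("high horizontal and low vertical gradient", max(|∂x| − |∂y|, 0)) is
  preserved as `gradient_mode = "subtract"`. The subtractive construction
  favors elongated structures and under-segments round nuclei — on
  synthetic data it keeps only the left and right arcs of each nucleus —
  so the magnitude form is the default.
* **Kernels.** Gaussian kernel 5×5 (σ = width/4), averaging kernel 9×9,
  3×3 square structuring element. None of these are dictated by the
  procedure; they are conventional sizes at this nucleus scale.
* **Binarization.** Otsu's threshold on the max-normalized gradient map
  by default; a fixed threshold is available. Whether the averaging
  smooth precedes or follows binarization is ambiguous in the original
  description; both orders are implemented
  (`binarize_order`), defaulting to smooth-then-binarize. The
  alternative order re-binarizes by majority vote after box-smoothing
  the binary image.
* **Closing the contour.** The gradient step leaves a thin ring around
  each nucleus whose contour lacks detail. The mask is therefore
  expanded once (`pre_dilate = 1`) and interior holes are filled
  *before* the four erosion rounds; otherwise the ring (half-thickness
  below 4 px) would be erased by the erosions rather than consolidated.
  After filling, a solid nucleus-sized region easily survives
  erosion×4/dilation×4, while sub-kernel speckle does not.
* **Boxes.** One minimal axis-aligned bounding box per external contour
  (connected component) with pixel area ≥ `min_contour_area` (default
  100 px²); nested contours (holes) are ignored; boxes are 0-based,
  half-open, sorted by (row, column) for determinism; no padding by
  default. Touching nuclei are *not* watershed-split: the interpretation
  criteria eliminate aggregates instead (below).

## Rule-based calling

Per crop, the nucleus mask is recomputed by Otsu thresholding of the DAPI
crop, hole-filling, and keeping the largest component — simpler and more
robust at crop scale than carrying the gradient-pipeline mask.

* **Spot counting** (`count_cep8_spots()`): fixed foreground threshold
  100 (spots render near 200, background near 15; Otsu is available but
  misbehaves on spot-free crops), connected-component labeling, area band
  4–200 px², and a border rule: a component counts when at least 50% of
  its area lies within the nucleus mask dilated by 3 px (about one spot
  radius), which admits boundary-clipped signals.
* **Positivity** (`assess_positivity()`): mean masked intensity ≥ 60
  (DAPI) or ≥ 80 (CD45). How CD45 positivity was quantified on-image in
  practice is not specified anywhere — staining is read visually — so the
  mean-intensity statistic and both thresholds are this package's
  operational decisions, calibrated once on the simulator (positive and
  negative populations sit near 140+ and 20).
* **Aggregates** (`detect_aggregate()`): a mask is excluded when its
  largest component has solidity (pixel area / Pick-corrected convex-hull
  area) below 0.94 or area above 1,100 px². Calibrated on the simulator:
  single discrete ellipses measure solidity 0.95–0.98 and area ≤ 750 px²,
  fused pairs typically fall below 0.94 and/or above 1,100. Heavily
  superposed pairs (small center distance) are nearly convex and escape
  the solidity test — a known limitation shared by any convexity
  criterion.
* **Precedence.** Exclusion overrides everything: excluded cells are
  labeled `excluded` and dropped from downstream scoring rather than
  counted as non-CTC, because the criteria eliminate them before
  interpretation.

## The CNN and transfer learning

`baseline3` is the three-hidden-block network: each block is convolution
→ ReLU → 2×2 max-pool, with the first block fixed at 32 kernels of 5×5.
Kernel counts for blocks two and three (64, 128 at 3×3) follow the
conventional doubling schedule, since only the first block is prescribed.
A single flatten + dense unit with sigmoid output gives the CTC
probability; 0.5 is the hard-label cut-off. VGG16/19, ResNet18/50 (with
batch normalization and projection shortcuts) and AlexNet are available
as configurations built at the requested input size; the desk-scale
experiments use `baseline3` only.

Unstated training details fixed here: Adam, learning rate 1e-3, batch
size 32, binary cross-entropy, He-normal initialization. Crops are
resized to a square input (64 px default; the test battery uses 32 px,
which keeps the 5-fold benchmark under a few CPU-minutes without hurting
AUC on this data). Which channels the classifier consumes is also
unstated; the default is all three (DAPI + CEP8 + CD45), because the CTC
definition depends on CD45 negativity — a classifier blind to CD45
cannot separate an aneuploid leukocyte from a CTC even in principle.
`channels_used` remains configurable for ablations.

Transfer learning follows the standard domain formalism: source and
target domains may differ in feature space or marginal distribution, and
tasks in label space. `transfer_init()` copies feature-block parameters
from a trained source model into a fresh target model and freezes the
first `frozen_depth` blocks; the classifier head is freshly initialized.
At desk scale no external pretrained weights are bundled: the source
model is trained on a disjoint synthetic auxiliary task (aneuploidy —
spot count ≥ 3 regardless of CD45 — on an unconditional cell mix), which
differs from the CTC task in both label function and marginal
distribution. The benchmark records per-epoch validation AUC for scratch
and transfer-initialized training over five seeds and compares the first
epoch at which each reaches the scratch model's final AUC; the
transfer-initialized model reaches it in strictly fewer epochs in the
median.

## Evaluation protocol

* **Stratified split** (`stratified_split()`): per class,
  ceiling(n × test_fraction) items go to test. Ceiling is the only
  rounding consistent with the published count arithmetic for a
  694 + 13,472 corpus at 20%: 0.2×694 = 138.8 → 139 and
  0.2×13,472 = 2,694.4 → 2,695, leaving 555 and 10,777 in training.
* **Down-sampling** (`downsample_majority()`): the training majority
  class is subsampled without replacement to the minority count
  (555 + 555 = 1,110 in that corpus). Whether re-balancing happened once
  before cross-validation or inside every fold is ambiguous; the default
  balances once on the full training partition (matching the published
  totals), and `balance = "per-fold"` re-balances within each fold's
  training set.
* **Cross-validation** (`kfold_cv()`): stratified folds (class counts
  within one item per fold), each item validated exactly once. The
  pooled report concatenates out-of-fold predictions; the mean of
  per-fold AUCs is also emitted, since the two aggregations differ in
  general.
* **ROC/AUC** (`roc_auc()`): thresholds swept over distinct scores with
  tied scores grouped into a single step, trapezoidal integration. With
  this tie handling the AUC equals the Mann–Whitney pair statistic
  (#{s₊ > s₋} + ½ ties)/(n₊ n₋) to machine precision, which the tests
  assert on random instances up to n = 200 against a brute-force oracle
  and against an independent ROC implementation (pROC).

## Numerical and degenerate-input choices

* All image intensities are 8-bit (0–255) at module boundaries;
  EBImage operations run on [0,1] internally.
* An all-background DAPI raster yields an empty mask with a warning (not
  an error); an empty mask yields zero boxes and zero crops.
* Otsu binarization max-normalizes its input first; a constant raster
  binarizes to all-zero.
* `roc_auc()` and `train_cnn()` refuse single-class inputs;
  `stratified_split()` refuses splits that would empty a class's training
  partition; `generate_image()` fails with a diagnostic when nuclei or
  disjoint spots cannot be placed (over-dense parameters).
* Determinism: every stochastic step is driven by an explicit seed
  (simulation, splits, down-sampling, fold assignment, weight
  initialization, batch shuffling); training is bit-reproducible in
  single-threaded BLAS mode, and the run manifest records the config
  hash and master seed.

## Benchmark problem sizes

The packaged benchmarks use: 125 images / 1,000 cells (balanced mix,
non-overlapping, default noise) for segmentation recall (≥ 0.9), rule
fidelity (≥ 99% agreement with ground truth on non-excluded cells), and
the pooled 5-fold `baseline3` AUC (≥ 0.95 at 32-px input, 6 epochs); 400
auxiliary-task crops for the transfer source; and 150/90 train/validation
crops × 5 seeds for the scratch-vs-transfer epoch comparison. These sizes
were chosen as the smallest at which the compared quantities are stable
across seeds.

## Known limitations

* Fixed intensity thresholds (spot 100, DAPI 60, CD45 80) are simulator
  calibrations; real acquisitions need per-batch recalibration or the
  Otsu options.
* Aggregate exclusion misses nearly-concentric superpositions and cannot
  split touching nuclei into separate calls.
* The CNN engine is single-threaded and CPU-oriented; the large named
  architectures are provided for structural completeness (parameter
  allocation, forward/backward, freezing) and are not tuned for
  large-scale training.
* ROC pooling across folds treats out-of-fold scores as comparable
  across models trained on different folds, which is conventional but
  optimistic when fold models are poorly calibrated relative to each
  other.
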