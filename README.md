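# ctcfish

Identification of circulating tumor cells (CTCs) in three-channel
immunofluorescence in-situ hybridization (imFISH) micrographs.

CTCs are rare tumor cells in peripheral blood whose count carries
prognostic value, but scoring them on fluorescence micrographs by eye is
slow and error-prone. After leukocyte depletion, candidate cells are imaged
in three channels: a DAPI nuclear counterstain (blue), a CEP8 chromosome-8
centromere probe (orange) whose punctate hybridization signals report
ploidy, and a CD45 leukocyte stain (red). The interpretation criteria are:

1. exclude aggregated or superposed nuclei and impurities,
2. DAPI-positive,
3. CD45-negative,
4. more than two CEP8 signal points,

i.e. a cell is a CTC iff it is **CD45⁻ / DAPI⁺ / CEP8 ≥ 3**.

The package implements the full computational pipeline around that rule,
for image analysts and method developers who want a testable, fully
seeded reference implementation:

* **simulate** — a synthetic imFISH image generator with complete ground
  truth (elliptical nuclei, 0–8 disjoint CEP8 spots per nucleus including
  boundary-clipped spots, CD45-positive/negative cells, overlapping nuclei,
  exposure gain and Gaussian noise), so every downstream stage can be
  benchmarked without patient data.
* **segment** — nucleus localization in the DAPI channel: Gaussian
  denoise → gradient extraction → binarize → averaging smooth → four
  erosions and four dilations → contour bounding boxes, mapped to all three
  channels.
* **rule_call** — CEP8 spot counting by connected components,
  mean-intensity DAPI/CD45 positivity, convex-hull solidity aggregate
  exclusion, and the CTC rule above.
* **model** — a compact CNN classifier (first hidden block: 32
  convolution kernels of 5×5, ReLU excitation, max pooling; two further
  blocks with 64 and 128 kernels; sigmoid output), plus VGG16/19,
  ResNet18/50 and AlexNet configurations and a transfer-learning
  initialization path with per-block freezing. Convolution and pooling
  kernels are compiled (Rcpp/RcppArmadillo); training is plain Adam on
  binary cross-entropy, deterministic under a fixed seed.
* **evaluate** — stratified 80/20 splitting with per-class ceiling
  rounding, majority-class down-sampling, stratified k-fold
  cross-validation, ROC/AUC (tie-grouped threshold sweep, trapezoidal
  integration, provably equal to the Mann–Whitney pair statistic), and
  confusion-matrix sensitivity/specificity at the 0.5 cut-off.

## Worked example

```r
library(ctcfish)
cfg <- pipeline_config(n_images = 12, ctc_prevalence = 0.3, seed = 7,
                       output_dir = "demo_run")
s <- run_pipeline(cfg)
jsonlite::toJSON(s, auto_unbox = TRUE, pretty = TRUE, digits = 4)
```

```
{
  "config_hash": "9459d794eb9b94d589883439a34c88b4",
  "seed": 7,
  "counts": {
    "images": 12,
    "cells_rendered": 96,
    "crops": 92,
    "calls": 92
  },
  "segmentation_recall": 1,
  "rule_sensitivity": 0.963,
  "rule_specificity": 1,
  "rule_agreement": 0.9888
}
```

Twelve simulated images contain 96 cells; segmentation finds 92 crops
(every true nucleus center falls inside a box — recall 1 — but a few
overlapping pairs merge into one box). The rule-based caller then labels
every crop:

```r
calls <- read.csv("demo_run/calls.csv")
table(calls$label)
#>      CTC excluded  non-CTC
#>       26        3       63
head(calls, 3)
#>       cell_ref dapi_positive cd45_positive cep8_count excluded   label
#> 1 img_0001_001          TRUE          TRUE          1    FALSE non-CTC
#> 2 img_0001_002          TRUE          TRUE          2    FALSE non-CTC
#> 3 img_0001_003          TRUE         FALSE          4    FALSE     CTC
```

Against the simulator's ground truth the calls reach sensitivity 0.963 and
specificity 1.0 (agreement 0.989); the three crops flagged `excluded` are
fused nucleus pairs, which the criteria eliminate before interpretation.
With `model = cnn_config(...)` the pipeline additionally trains the CNN on
a down-sampled balanced training partition with 5-fold cross-validation
and writes ROC/confusion reports.

A thin command-line wrapper is installed under
`inst/scripts/ctcfish` (subcommands `simulate`, `segment`, `call`, `run`).

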