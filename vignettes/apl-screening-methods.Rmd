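---
title: "Methods: morphology-based APL screening with aplScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphology-based APL screening with aplScreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

aplScreen implements a three-stage screening pipeline for acute
promyelocytic leukemia (APL) on stained peripheral blood smear microscopy:
leukocyte focusing, six-class leukocyte classification with a compact
channel-attention CNN, and rule-based risk stratification with an advisory
diagnostic opinion. This vignette records the models, the parameters that
matter, the numerical choices, and what the synthetic test bed does and does
not establish.

## 1. Leukocyte focusing

**Color normalization.** Field appearance varies with staining batch and
illumination. `normalizeColor()` matches per-channel means and standard
deviations of a field to reference statistics, by default in Reinhard's
l-alpha-beta space (RGB -> LMS by a fixed 3x3 matrix, log10, then the
decorrelating rotation), the standard recipe for stain-appearance transfer;
a plain `rgb` option exists. A channel with zero spread cannot be rescaled
and is set to the reference mean. The transform is idempotent up to 8-bit
quantization (a second pass moves no pixel by more than one level).
Normalization is off by default in `runPipeline()` because the synthetic
fields come from a single simulated staining batch; enable
`normalizeToReference` for heterogeneous material.

**Stain separation.** Romanowsky-type stains combine a basic, nucleus-avid
dye (methylene blue) and an acidic, cytoplasm/red-cell-avid dye (eosin).
Under Beer–Lambert, per-channel optical density
`OD_c = -log((I_c + eps) / I0)` is linear in the stain amounts:
`OD = t(V) %*% s` with `V` the 2x3 unit stain matrix. `deconvolveStains()`
solves per pixel by least squares and clips negatives. Numerical choices:

* `I0 = 255`, `eps = 1/255` — avoids `log(0)` on 8-bit input. The forward
  synthesis used by the generator, `I = I0 * exp(-OD) - eps`, is the exact
  inverse, so the continuous round trip is exact to ~1e-12 over the whole
  working range (densities up to 3).
* Default stain vectors: methylene blue (0.644, 0.717, 0.267), eosin
  (0.093, 0.954, 0.283), unit-normalized; both overridable via
  `stainModel()` or estimable from single-stain control fields with
  `estimateStainVectors()`.
* Near-parallel stain vectors make the 2x2 normal system singular; the
  constructor rejects dependent rows and `deconvolveStains()` rejects
  marginal cases (cross-product norm below 1e-3) by name.

**Dynamic-range limit (known and intended).** After 8-bit quantization a
channel rendered at few counts carries almost no density information:
rounding a pixel stored in 2/255 counts perturbs its OD by ~0.26, and no
estimator can undo that. Quantized round trips are accurate to better than
0.02 wherever every channel's OD stays below ~1.7 (intensity above ~47
counts); outside that range errors grow smoothly and reach ~0.26 at the
extreme corner (both densities 3). The synthetic generator therefore caps
densities at 2.0 (methylene blue) and 1.4 (eosin), keeping its noise-free
fields recoverable to better than 0.05 everywhere.

**Binarization and boxes.** The methylene-blue density map is thresholded
(Otsu on the normalized map by default, fixed threshold optional), opened
with a small box brush (diameter 3: preserves compact nuclei, removes
speckle without severing thin inter-lobe bridges), hole-filled, and filtered
by component area. Two guards matter in practice:

* a density floor (`minDensity = 0.2`, also a lower bound on the Otsu
  threshold) makes signal-free maps — e.g. red-cell-only fields — yield an
  empty mask instead of letting Otsu split noise;
* `minArea = 400` px (at the generator's scale: cell radii 24–32 px,
  nuclear regions >= ~600 px) removes granule satellites and debris.

Connected components are 8-connected (C++ BFS labelling, raster-deterministic
label order); boxes are 0-based, half-open, sorted by (y0, x0). Crops are
padded by 15% per side, squared with the image's modal background color (no
anisotropic stretch), and resized to 224x224 for the classifier.

## 2. The compact channel-attention classifier

Four convolution blocks — 3x3 conv (stride 1, 1, 2, 1; channels 64, 128,
256, 256), channel normalization, ReLU, 3x3/2 max pooling — map a 224x224x3
crop through feature maps of side 112, 56, 14, 7. A squeeze-and-excitation
(SE) module on the final 7x7x256 map pools each channel to a scalar, gates
through a 16x bottleneck (`softmax(W2 %*% relu(W1 %*% s))`) and rescales the
channels. Two fully-connected layers (12544 -> 512 -> 6) with dropout 0.5
after each produce the logits. The canonical parameter count is exactly
7,396,886 (7.397 M) — reproduced only when conv layers carry biases *and*
the normalization carries per-channel scale/shift pairs — and the
multiply–accumulate count is 1.3648e9 per input (1.3914e9 counting
normalization/ReLU/pool/SE elementwise work); `modelAccount()` prints the
per-layer table.

**Engine.** No deep-learning framework is used: forward and backward passes
are implemented in C++/Armadillo (float32), with convolutions as im2col +
BLAS `sgemm` in a pixel-major (L x C) layout so all per-channel work touches
contiguous memory. Gradients of every tensor type are verified against
central finite differences in the test suite. Evaluation-mode inference is
RNG-free and bitwise reproducible.

**Normalization inside blocks.** Feature standardization uses per-sample
spatial (instance) statistics with learned scale/shift, rather than
cross-sample batch statistics. This keeps the parameter count identical,
makes evaluation independent of batch composition (bitwise-deterministic
predictions), and permits per-sample gradient accumulation in bounded
memory. With 50k–3k spatial positions per channel the statistics are close
to batch statistics in practice; this is a deliberate design choice of this
implementation.

**SE gate.** The softmax gate normalizes the 256 channel weights to sum to
one, so the attention output is scaled by ~1/256 on average. A sigmoid gate
(the convention of the original SE design) is available by configuration;
ablation tests exercise both. Which gate the published architecture truly
trained with is not decidable from the printed description; the package
defaults to softmax as printed.

**Initialization.** Kaiming-normal weights, zero biases, unit scales —
plus an LSUV-style variance calibration: at build time inside
`trainModel()`, a 32-image probe batch is forwarded through the frozen conv
stack and the two FC layers are rescaled so their pre-activation standard
deviations are ~1. Without this, the softmax gate's 1/256 shrinkage leaves
the FC path with vanishing gradients for several epochs; with it, the
canonical net reaches useful accuracy within one epoch on the synthetic
classes. Calibration touches only the initial state; it is not an extra
training signal.

**Optimization.** SGD with momentum 0.9 (PyTorch convention:
`v' = m v + g`, `w' = w - lr v'`), initial learning rate 5e-3 divided by 5
every 10 epochs, dropout active only in training, softmax cross-entropy
loss, non-finite loss aborts with a diagnostic. Defaults: 30 epochs, batch
size 32, one seed controlling split, init, oversampling, augmentation and
dropout. Because gradients are accumulated per sample, batch size changes
the update frequency but not the arithmetic cost per epoch; the learning
smoke test uses batch size 8 (4x more updates per epoch), which from-scratch
convergence at n = 600 needs.

**Ablations.** `ablationConfig()` builds the published variants: no SE, no
dropout, and 2- or 3-block prefixes whose first FC width is re-derived from
the resulting feature-map geometry (the variant tables print no
architecture, so the canonical prefix rule is this package's).

## 3. Protocol and metrics

`stratifiedKFold()` assigns each class's samples to 5 folds within one
sample of class-size/5; round r tests on fold r, validates on the next fold
cyclically, trains on the rest, so the five test folds cover the data
exactly once. Class imbalance is handled by per-epoch oversampling of
minority classes to the majority frequency, every presented sample passing
through random horizontal/vertical flips and rotations by multiples of 90
degrees (right angles avoid interpolation artifacts and border fill;
arbitrary angles are deliberately not default). Checkpoint selection: best
validation accuracy, earliest epoch on ties.

Metrics follow the standard one-vs-rest table: TPR (sensitivity), TNR
(specificity), FPR, FNR, precision and F-beta (beta = 1 by default; the
weighted F averages per-class F values by support — computing F from
weighted precision/recall instead changes the 4th decimal and is available
via the per-class table). Weighted averages use true-class support;
undefined ratios (zero denominators) are excluded with a warning and the
weights renormalized. ROC/AUC uses a threshold sweep with trapezoidal
integration, tie-grouped; the weighted AUC averages by support.

Model comparison uses the Friedman rank test (mid-ranks for ties, textbook
chi-square statistic with k-1 degrees of freedom; an exact permutation p is
available for small tables) and the Nemenyi critical distance
`CD = q_alpha(k) sqrt(k(k+1)/(6N))` with `q_alpha(k)` from the studentized
range at infinite df divided by sqrt(2) (`qtukey`), e.g. q = 2.569 at
alpha = 0.05, k = 4, giving CD = 1.915 at N = 6.

## 4. Risk stratification and opinion

The Sanz/PETHEMA–GIMEMA score partitions the CBC quadrant: high risk when
WBC > 10 x10^9/L; otherwise low when platelets > 40 x10^9/L, else
intermediate (boundaries inclusive as printed). An opinion flags suspected
APL when at least `minPromyelocytes` (default 1) cells are classified as
promyelocytes; suspected cases carry the advisory treatment string
("ATRA + arsenic", plus "+ chemotherapy induction" at high risk). Every
opinion carries a fixed not-for-clinical-use disclaimer; the threshold is
configurable because a single false-positive promyelocyte on a healthy
smear would otherwise flag it — at the default the pipeline is maximally
sensitive, which is the stated clinical posture for APL screening.

## 5. The synthetic test bed

`generateSmear()` renders fields as stain-density compositions pushed
through the same Beer–Lambert forward model the deconvolution stage
inverts: red cells are pale eosin disks with central pallor; leukocytes
(radius 24–32 px at field scale) carry class signatures — round high-ratio
lymphocyte nuclei; 3–5 overlapping neutrophil lobes; kidney-shaped monocyte
nuclei; bilobed eosinophil nuclei with coarse bright eosin granules;
basophils obscured by dense blue granules; promyelocytes 1.25x larger with
eccentric kidney nuclei, heavy purple (two-dye) granulation and 1–2
rod-shaped inclusions. Gaussian pixel noise (sd 2 of 255 by default) is
added before quantization. Cells are placed by rejection sampling without
overlap (an `allowOverlap` flag exists solely to demonstrate the known
failure mode of dense smears); a retry cap turns impossible packings into
an error. All randomness flows from the recipe seed; identical recipes give
bitwise-identical images.

Ground truth is generative: each leukocyte's box is the bounding box of its
own methylene-blue density above 0.3 — the same signal the focusing stage
segments — with the pixel count as area. Default study conditions for the
focusing properties: 20 fields of 384x384 with 10 leukocytes and 60 red
cells each.

`generateCellDataset()` renders centered single cells into classifier-ready
crops (balanced, or following an explicit class-size vector for imbalanced
designs). The class signatures were tuned, before any classifier runs were
scored, so that a nearest-centroid baseline on simple color/texture
features separates them well — the generator's job is to be *learnable*,
so that training failures indicate implementation bugs rather than an
impossible task.

**What passing these tests shows — and does not.** The synthetic bed
verifies the machinery: stain separation inverts its forward model;
focusing finds what was planted; the network can fit cleanly separable
classes from scratch under the stated optimizer; the protocol and metric
layers are exact. It does not emulate real smear statistics (illumination
and focus artifacts, stain batch drift, touching and overlapping cells,
morphological ambiguity between activated lymphocytes, monocytes and
variant promyelocytes), so accuracy on these fixtures says nothing about
clinical accuracy. Published-figure reproduction in this package is
restricted to exactly recomputable quantities: architecture accounting, the
metric layer applied to the printed clinical confusion matrix, the critical
distance, and the risk/treatment rules.

## 6. Problem sizes used by the test suite

Chosen as the package's own verification conditions: the learning smoke
test trains the canonical 224x224 network on 600 synthetic crops
(100/class, 80/20 train/validation split, batch 8, up to 20 epochs with
early stop once validation accuracy reaches 0.98); the no-SE and no-dropout
ablations train one epoch on a 30-crop subset at 224; the 2-/3-block
variants train their epoch at a 64-px input, because with fewer pooling
stages the re-derived first FC at 224 would hold 205 M parameters
(56x56x128 flattened) — the input-size-independent geometry rule and
trainability are what the check certifies; focusing recall uses 20 default fields (200
cells); protocol invariants run on the published clinical class sizes
(6,814 labels); cross-validation mechanics run on 108 32x32 crops with a
reduced architecture. On one CPU core the full suite completes in roughly
a quarter hour, dominated by the smoke test.

## 7. Known limitations

* Overlapping or touching cells are segmented as one component by design;
  splitting them is out of scope.
* The stain matrix is a fixed prior, not estimated per slide; strongly
  divergent staining requires `estimateStainVectors()` on control fields.
* Instance statistics in place of batch statistics, and the variance
  calibration at init, are implementation choices a framework-based
  reimplementation would not need; they are documented here because they
  affect training dynamics, not the model's parameter count or inference
  contract.
* The advisory opinion is a screening aid; confirmation (flow cytometry,
  molecular genetics) is outside the package's scope.
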