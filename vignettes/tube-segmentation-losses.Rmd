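---
title: "Compound segmentation losses for tube-tip localization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compound segmentation losses for tube-tip localization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

An endotracheal tube (ETT) on a portable chest radiograph is a thin, faintly
radiopaque curve a few pixels wide, descending from the top of the image to
its inferior endpoint — the *tip*, whose distance to the carina decides
whether the tube is safely placed. Automating tip localization is usually
cast as binary segmentation followed by landmark extraction: a network
predicts a per-pixel tube probability, the probability map is binarized, and
the tip is read off the segmented tube. Two properties make the segmentation
problem unusual. First, extreme class imbalance: the tube occupies on the
order of 1% of the pixels. Second, the quantity that matters clinically is
not overall overlap but the position of one endpoint, so small errors at the
inferior end of an otherwise good segmentation dominate the useful error
metric.

This package implements the full pipeline — losses, network, preprocessing,
tip extraction, evaluation, and a synthetic data generator — so the central
scientific question (*which training loss, or which combination, best serves
segmentation-then-localization?*) can be studied end to end on a single CPU
with no external data.

## Loss families

Let \(x\) be the per-pixel logit, \(\sigma(x)\) its sigmoid, \(p\) the
predicted probability and \(y \in \{0,1\}\) the ground truth.

**Distribution-based losses** treat pixels as labelled samples:

- *BCE*: \(-[p_c\, y \log\sigma(x) + (1-y)\log(1-\sigma(x))]\), evaluated
  from logits in the fused log-sum-exp form so saturated logits cannot
  overflow. `pos_weight` (\(p_c\)) trades precision for recall.
- *Focal*: \(-(1-p_t)^\gamma \log p_t\) with \(p_t = p\) if \(y=1\) else
  \(1-p\); the modulating factor silences easy background pixels
  (\(\gamma = 2\) by default, the conventional value from the focal-loss
  literature).
- *MCC*: one minus the Matthews correlation computed from soft confusion
  sums \(TP=\sum py\), \(FP=\sum p(1-y)\), \(FN=\sum(1-p)y\),
  \(TN=\sum(1-p)(1-y)\), with an \(\epsilon = 10^{-6}\) guard under the
  square root. The multi-class \(R_K\) statistic specializes to this
  binary form; we implement the binary specialization directly. For a
  one-class target the guard yields correlation 0 (loss 1) — a documented
  degenerate value, not an error, since no correlation is defined there.

**Region-based losses** compare predicted and true foreground as sets:

- *Dice*: \(1 - (2\sum yp + s)/(\sum y + \sum p + s)\),
- *Jaccard*: \(1 - (I + s)/(U + s)\) with \(I=\sum yp\),
  \(U = \sum y + \sum p - I\),
- *Tversky*: \(1 - (TP + s)/(TP + \alpha FP + \beta FN + s)\); defaults
  \(\alpha = 0.3, \beta = 0.7\) penalize missed tube pixels harder, the
  conventional choice from the Tversky-loss literature.

The smoothing constant \(s\) (default 1) sits in numerator and denominator,
so a correctly empty prediction scores a perfect 0 instead of 0/0. Region
sums pool the whole training batch as one set rather than averaging
per-image losses; for images whose foreground is a few hundred pixels this
markedly stabilizes early training (a per-image switch is provided).

**Compound losses** are weighted sums of one distribution and one region
loss — nine pairs in total. The default weighting is the unweighted sum
\((1, 1)\); the weights are configurable. The two families see the same
prediction through different views (logits vs probabilities), which the
`prediction_batch` container carries jointly.

Reduction semantics for the pixel-wise losses: the per-batch-element value
is the mean over that element's pixels; `"mean"` averages those (equal to
the overall per-pixel mean for equally shaped elements), `"sum"` sums them,
`"none"` returns the per-element vector.

## The network

The segmenter is a U-Net++: an encoder--decoder whose skip pathways carry
chains of convolution nodes. Node \(X^{i,j}\) (level \(i\), chain position
\(j\)) receives all earlier same-level nodes \(X^{i,0..j-1}\) plus the
upsampled \(X^{i+1,j-1}\); nodes exist for \(i + j \le d - 1\), giving
\(d(d+1)/2\) nodes at depth \(d\). Each node is a
[conv 3×3 → batch-norm → ReLU] ×2 block; downsampling is 2×2 max pooling;
upsampling is bilinear ×2 followed by a 1×1 convolution to match channel
widths (parameter-light and shape-safe under concatenation). Optional deep
supervision attaches a 1×1 sigmoid head to every top-row node; training
averages the per-head losses and inference always reads the final head
\(X^{0,d-1}\).

There is no deep-learning framework on the target platform, so the network,
its initialization (Kaiming-uniform, seeded) and the full backward pass are
implemented in the package: convolutions as im2col patch matrices times
flattened kernels (single-precision GEMM inside the compiled kernel — the
conv touches each input element nine times, so halving its memory traffic
roughly doubles single-CPU throughput; everything else is double
precision), with hand-derived gradients for convolution, batch norm,
pooling, upsampling and every loss. All gradients are verified against
central finite differences in the test suite.

Encoders are pluggable by name (`register_encoder()`); the default `plain`
encoder is the per-level double-conv block above. Pretrained backbones
(RegNet/ResNet class) are deliberately out of scope — there are no
pretrained weights to load offline — but the hook means a backbone can be
added without touching the graph code.

## Preprocessing and augmentation

Raw radiographs are downscaled by non-overlapping 3×3 max pooling (max, not
mean, so the thin bright tube survives), then center-cropped — the ETT runs
through the central mediastinal band. Training-time augmentation draws, in
fixed order: horizontal flip (p = 0.5), one affine transform (scale uniform
in 85–115%, rotation ±5°, translation ±10% of each dimension — read as a
fraction of image size), and CLAHE on the image only (clip limit uniform in
(1, 4), p = 0.7, 8×8 tiles). Image and mask receive the identical geometric
transform — bilinear for the image, nearest-neighbour for the mask, zero
fill — and the mask is re-binarized. Validation and test data get pooling
and cropping only. The affine and CLAHE operators are EBImage's; the
recipe, ordering and joint image/mask bookkeeping are the package's.

Coordinates are 1-based `(row, col)` with row 1 at the image top, the
natural R convention; the manifest stores tip coordinates accordingly.

## Tip extraction and evaluation

Evaluating localization needs a tip from a probability map; no standard
extraction rule exists, so the package defines one: binarize at
0.5, keep the largest 8-connected component, and take the most inferior
pixel (maximal row) as the tip, breaking row ties at the lower median
column. Anatomically the tube descends the trachea, so its inferior
endpoint is the tip; the largest component suppresses small spurious
detections. If nothing exceeds the threshold the result is an explicit
failure sentinel: the image counts in PSE denominators, its distance is
recorded as infinite, and summary mean distances average the finite values
while reporting the failure count separately.

Metrics: IOU (with the both-empty case scored 1 — perfect agreement on
absence), Euclidean tip distance in cm (pixel spacing from the manifest),
and PSE — the percentage of samples with distance strictly below each of
{0.25, 0.5, 1, 1.5, 2} cm.

## The phantom generator

Real annotated radiographs cannot ship with the package, so the generator
emulates exactly the features of the data contract that the loss comparison
exercises: a dark background with smooth low-frequency intensity variation
(a few random cosine modes), a single bright tube — a quadratic Bézier curve
from the top edge to a tip at 55–90% of image height, 2–4 px wide, with a
1-px feathered edge — bright distractor artifacts (short line segments and
soft blobs) that stay out of the tip's neighbourhood so the ground truth
stays unambiguous, and additive Gaussian noise (σ = 0.03). Foreground
fractions land in the 0.1–6% band: the class-imbalance regime that
motivates comparing Focal/Tversky/MCC in the first place. Pixel spacing is
0.05 cm/px, so the 5-px tip-error scale corresponds to the 0.25 cm PSE
threshold.

What the phantoms do *not* model: anatomy (ribs, lung fields, other
devices), detector physics, multiple catheters, or the carina. Passing the
end-to-end study on phantoms therefore demonstrates that the training
machinery, losses and localization pipeline work and can be compared
fairly — it does not certify clinical performance on radiographs.

The generator is bit-deterministic per seed, and per-sample seeds are
derived from the master seed so any single sample regenerates in isolation.

## The study harness

`kfold_split()` shuffles ids and rotates near-equal blocks: fold *i* tests
on block *i*, validates on block *(i* mod *k)* + 1 and trains on the rest —
at *k* = 5 the familiar ≈60/20/20 proportions. Training uses Adam
(lr 10⁻³, batch 4, 10 epochs in the desk-scale profile), keeps the
checkpoint with the best validation
IOU, and aborts with a diagnostic naming the loss family and epoch if a
loss goes non-finite. `compare_losses()` runs every (loss, fold) cell,
catches and reports per-cell failures without losing the partial report,
and assembles per-cell, per-loss, PSE and family-average tables.

The canonical desk-scale profile (`study_profile()` / `run_study()`) is 64
phantoms at 96×96, a depth-3 base-8 U-Net++ (≈58k parameters) with deep
supervision, and folds 1–2 of the 5-fold split over seven losses: the four
headline losses (dice, focal, mcc-tversky, bce-dice) plus the single-loss
parents of the two compounds, so compound-versus-parent comparisons can be
read from one report. Problem sizes were chosen so the whole study trains
in minutes on one CPU while leaving every loss clearly above chance.

Design choices worth recording:

- *Class-prior head initialization.* Every prediction head's bias starts at
  `qlogis(0.1)`, so the untrained model predicts a low foreground
  probability rather than 0.5 everywhere — the standard stabilizer for
  one-stage training under extreme imbalance (introduced with the focal
  loss). The value sits deliberately an order of magnitude *above* the
  phantoms' ~1--3% foreground fraction: pilot runs showed two opposite
  failure modes. Starting at 0.5, the set-statistic losses (MCC and its
  compounds) occasionally rose briefly and then decayed without recovering
  inside the 10-epoch budget; starting at the exact prior, the plain BCE
  loss — whose per-pixel mean is nearly minimized by predicting the
  marginal — sat in a flat region and sometimes never crossed the 0.5
  threshold at all. At 0.1 every loss family trained reliably across
  seeds. Configurable (`head_bias_prior`; `NULL` restores the generic
  random bias).
- *Gradient-norm clipping.* The global gradient norm is capped at 5 before
  each Adam step (`clip_norm`), the routine guard against an occasional
  destabilizing batch; it leaves well-scaled steps untouched.
- *Deep supervision on, in the study profile.* In pilot runs on phantoms
  the auxiliary heads made
  little difference to mean IOU but visibly stabilized tip localization for
  the weakest (MCC-based) cells across seeds — consistent with their role of
  shortening gradient paths into the decoder. Inference is unchanged (final
  head only), and the per-head losses are averaged.
- *Two folds, not a degenerate 2-fold split.* Under the rotation rule a
  literal k = 2 split has no training block left; the desk-scale profile
  therefore runs folds 1–2 of the standard 5-fold split, preserving the
  60/20/20 shape.
- *Checkpoint selection by validation IOU* mirrors the reporting metric.
- *Determinism.* Everything — weight init, shuffles, augmentation draws,
  phantom sampling — derives from one seed through R's RNG; the compiled
  kernels are single-threaded and allocation-free of randomness, so a rerun
  reproduces the comparison report bit for bit on one CPU.

## Numerical notes and limitations

- BCE/Focal gradients are evaluated through softplus/log-sigmoid forms;
  stable for |logits| ≫ 100.
- The MCC loss on an all-one-class target returns exactly 1 (correlation 0
  via the ε guard); training batches in the imbalance band never hit this.
- Batch norm uses biased batch variance in the normalizer and unbiased
  running variance (momentum 0.1) for inference, matching common practice;
  it can be disabled for very small batches.
- Bilinear upsampling uses half-pixel centres with clamped borders; its
  adjoint is the exact transpose, which the gradient checks cover.
- The conv kernels accumulate in single precision; losses, batch norm and
  optimizer state stay double. Relative gradient error against double
  finite differences is ~10⁻³ at worst, far below the noise scale of
  stochastic training.
- Max pooling breaks argmax ties toward the earliest pixel in column-major
  order; tie inputs are measure-zero for continuous images.
- `extract_tip` on a fragmented prediction follows the largest fragment;
  if the true tube splits into pieces the reported tip can sit mid-tube.
  This is intrinsic to any component-based rule and is visible in the tip
  distances of weakly trained cells.
- The phantom study shows *relative* loss behaviour under thin-structure
  imbalance; absolute IOU/distance values on clinical radiographs with
  pretrained encoders are out of scope by design.
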