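---
title: "Confidence-aware evaluation of skin ultrasound classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-aware evaluation of skin ultrasound classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-frequency ultrasound (HFUS, 20–75 MHz) resolves the layered anatomy of
skin: the probe membrane, coupling gel, the bright epidermis band, a possible
subepidermal low echogenic band (SLEB, characteristic of inflammatory disease
such as atopic dermatitis), the speckled dermis, and muscle. A CNN can
classify such images into diagnostic groups with high accuracy and still be
untrustworthy: its evidence may sit in the gel or the probe membrane rather
than in the tissue a dermatologist would examine. `usconf` quantifies that
mismatch. It scores each classification by how much of the network's saliency
(Grad-CAM) falls inside anatomically relevant skin layers, and it evaluates
whole models by how well accuracy, confidence and dataset coverage can be
traded off.

## The pipeline

For an image with an epidermis mask (ground truth or produced by the built-in
segmenter):

1. **Skin layer map (SLM).** Per column, epidermis pixels get the maximal
   relevance 3; below the epidermis the value decreases twice by 1 every
   0.5 mm and then twice by 0.5 every 0.5 mm (the combined epidermis + dermis
   thickness of interest is under 2 mm), so depth `d` mm below the lowest
   epidermis pixel maps to 2, 1, 0.5, 0 in consecutive 0.5 mm bands and −1
   beyond 2 mm. A 30-pixel gel band directly above the epidermis is 0;
   everything above it, and every column without epidermis, is −1 (avoided:
   membrane, remaining gel, muscle). Depth is measured per column on
   pixel-centre coordinates, `(r − boundary_row) · axial_res`; skin layers
   are treated as locally parallel, which the undulating phantom epidermis
   exercises. The first 0.5 mm band below the epidermis takes value 2, so the
   epidermis is uniquely maximal in the map.

2. **ROI extraction.** Five modes crop the image around the epidermis:
   mode 0 none; mode 1 keeps 30 px above the top epidermis pixel; mode 2
   keeps 1 mm; modes 3 and 4 add a lower crop 2 mm below the bottom pixel to
   modes 1 and 2 respectively. "Top" and "bottom" are global extremes over
   all columns, so crops are rectangular; mm margins convert to pixels
   through the axial resolution, rounded to nearest. In modes 1–4 every
   retained pixel whose SLM value is −1 is set to 0, keeping one source of
   truth for avoided regions. Mode 0 is a pure passthrough.

3. **Grad-CAM.** For target class `c` (the predicted class, also for
   misclassified samples) with pre-softmax score `y_c` and final
   convolutional feature maps `A^k` of `Z` positions,
   `alpha_k = (1/Z) sum_ij d y_c / d A^k_ij` and the raw map is
   `ReLU(sum_k alpha_k A^k)`. Maps are min–max normalized to [0, 1] per
   image (an all-constant map, "no localized evidence", normalizes to all
   zeros), then bilinearly rescaled to the ROI grid and placed at the ROI
   offset inside a zero canvas of the original size. Normalization before
   rescaling is order-insensitive here because bilinear interpolation cannot
   leave [0, 1].

4. **Classification confidence level (CCL).** With `L` the aligned map and
   `H` the SLM, the confidence map collects the strictly positive products
   `L(i,j) · H(i,j)`; the CCL `t` is their mean over the `M` included pixels.
   Strict positivity means pixels with `H <= 0` (gel, avoided) and pixels
   with no saliency never contribute. `t` ranges over [0, 3]. The mean is
   undefined at `M = 0`; we define `t = 0` there — no evidence inside
   relevant anatomy is minimal confidence.

5. **Multicriteria model evaluation.** Given per-sample CCLs and
   correctness flags over a dataset of size `N`, for each percentile
   `p = 1..99` the threshold `t_p` is the p-th percentile of CCL values; the
   `n_p` samples with CCL strictly greater are kept, their accuracy is
   `a_p`, and `m_p = a_p · (n_p/N) · t_p`. The model measure is
   `m = max_p m_p`, attained at `p_opt`. High `m` requires high accuracy
   with high anatomical confidence over a large fraction of the data.

## Numerical and design choices

* **Percentile method.** Linear interpolation between order statistics
  (`stats::quantile` type 7), exposed as an argument because `m` is
  threshold-sensitive; a nearest-order-statistic variant is available.
  Strict `>` thresholding is kept exactly as the definition states, with the
  documented degenerate consequence that a single-sample dataset always
  yields `m = 0` (every percentile equals the sample's own CCL).
* **Empty subsets.** `a_p` on an empty subset is 0, so such points are never
  selected as the optimum. Ties in `m_p` break to the smallest `p`, i.e. the
  largest retained dataset.
* **Percentiles over the pooled dataset.** CCL thresholds are computed over
  all test-fold predictions pooled together (the evaluation's dataset-level
  definition); a leakage-safe per-fold variant can be obtained by running
  `evaluate_model()` per fold.
* **M = 0 logging.** Samples with `M = 0` appear with `t = 0` in the
  per-sample table, so they are visible rather than silently dropped.
* **Upscaling** is bilinear with corner alignment, so saliency peaks move by
  at most half an output pixel relative to the exact geometric mapping.

## The network engine

No deep-learning framework is assumed: the package ships a small
convolutional-network engine (stride-1 same-padding convolutions evaluated as
im2col patch-matrix products, ReLU, 2×2 max pooling, nearest-neighbour
upsampling with additive U-Net-style skip connections, dense heads, SGD with
momentum). Backpropagation is analytic and exposes the gradient of any class
score with respect to any intermediate activation, which is exactly what
Grad-CAM needs; its correctness is pinned by finite-difference tests at
relative tolerance 1e-3 and tighter.

* **Classifier** (per CV fold): 3 conv blocks (8, 16, 16 filters with two
  2×2 poolings), a dense 4-class head; inputs are ROI images bilinearly
  resized (aspect-distorting) to 32×32 and z-scored per image. Cross-entropy
  loss, SGD momentum 0.9, learning rate 0.01, batch 8, 12 epochs. Grad-CAM
  hooks the last spatial layer (8×8). The occasional weight draw kills all
  ReLU paths and training collapses to one class; training therefore checks
  resubstitution accuracy and re-initializes with a derived seed (at most
  twice).
* **Segmenter**: a 3-level encoder–decoder (8/16/16 filters) with additive
  skip connections, per-pixel softmax, weighted generalized Dice loss with
  inverse-squared-volume class weights (`1/(sum t_c)^2`) to absorb the
  epidermis/background imbalance; equal-weight Dice and cross-entropy are
  selectable. Inputs are z-scored per image. Dice-type losses have an
  all-background local optimum near loss 0.85; runs stuck above 0.8 after
  three epochs are aborted and re-initialized. A fraction of the training
  samples (15%) is held out and the returned weights are those with the best
  validation Dice, checked every 5 epochs. Predictions keep only the largest
  connected component — downstream SLM/ROI geometry assumes a single band —
  and an empty prediction raises an error instructing the caller to fall
  back to the ground-truth mask or skip the sample; the experiment pipeline
  skips and logs such samples and fails only if more than 10% are skipped.

## The phantom generator

Real HFUS data cannot be redistributed, so all experiments run on seeded
synthetic phantoms that emulate the axial anatomy: a thin bright membrane
line, dark gel, a bright epidermis band with a sinusoidal top boundary
(amplitude 0.1 mm — so per-column SLM logic is non-trivially exercised),
class-specific structure, speckled dermis and a darker muscle zone. The four
classes differ as a dermatologist would expect at a caricature level: AD has
a 0.5 mm SLEB, psoriasis a 1.8× thickened epidermis plus a thinner (0.2 mm)
SLEB, tumour a hypoechoic disk in the dermis, control none of these. Region
intensities are fixed and ordered (membrane 0.95 > epidermis 0.85 > dermis
0.55 > SLEB 0.15 ≥ gel 0.05); speckle is multiplicative with a Rayleigh
field of unit mean, blended by `speckle_scale` (default 0.6, a visually
heavy but separable level). The default grid is 256×256 at 0.02 mm/px
axially, so the 2 mm of diagnostically relevant tissue spans about 100 rows
— the full-scale geometry at desk scale. Per-patient log-normal offsets on
thickness and depth parameters correlate the images of one patient, which is
what makes patient-wise cross-validation meaningful. Since published
cohorts do not quantify typical SLEB thickness or contrast, these defaults
are plausible rather than calibrated values.

What the phantoms deliberately do not model: physical wave propagation,
B-mode beamforming, probe-angle artifacts, intensity inhomogeneity, or
lesion texture. Passing tests on phantoms therefore demonstrates the
correctness and internal consistency of the framework — not clinical
performance of the small built-in networks.

## Experiment pipeline and problem sizes

`run_experiment()` generates a dataset, builds SLMs, extracts ROIs, and runs
patient-wise k-fold cross-validation: whole patients are dealt class-sorted
round-robin into test folds (approximately class-balanced), the remaining
patients split 8:1 into training and validation by patient, a classifier is
trained per fold, and every test image receives a prediction, a Grad-CAM map
aligned back to original coordinates, and a CCL against its SLM. Pooled
per-sample results feed the percentile sweep; reports include full and
p_opt-limited confusion matrices in the fixed class order AD, psoriasis,
tumour, control.

Augmentation follows two modes: `Aug0` draws horizontal reflections and
±10 px translations (zero padding); `Aug1` additionally rotates by an angle
uniform in ±20° (bilinear, zero fill). Transforms are applied to the ROI
image before resizing to the classifier input.

The standard problem sizes used by the package's own tests and the
acceptance script are 400 phantoms (100 per class, 10 patients per class)
with 10-fold patient-wise CV for classification, and 50 training / 10
held-out phantoms at 96×96 (0.045 mm/px) for segmentation, where the
trained segmenter reaches mean Dice well above 0.9 and the classifier
reaches held-out accuracy above 0.9. At these sizes a full experiment runs
in a few minutes on one CPU core.

## Known limitations

* The engine is plain R; it is sized for desk-scale experiments, not for
  2000×1500-pixel clinical images. Full-scale backbones can be plugged in
  behind the same model handles.
* CCL is an anatomical-agreement score, not a calibrated probability.
* The SLM makes no tumour-specific adjustment: layers below a tumour are
  graded by the same depth rule, and bands inside lesions are not treated
  specially.
* Exact grid alignment between the Grad-CAM canvas and the SLM is mandatory;
  mismatched resize policies are rejected rather than reconciled.
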