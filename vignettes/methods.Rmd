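---
title: "Capacity-controlled separable-attention CNNs for brain-MRI classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the models and procedures the package
implements, the parameters that matter, and the design decisions taken
where the problem left genuine freedom. It states no empirical result
beyond what the test suite and `scripts/acceptance.R` themselves
compute.

## The problem

Four-class image-level classification of brain MRI slices (glioma,
meningioma, pituitary adenoma, no tumor) from class-folder datasets.
Public corpora of this kind carry two methodological hazards: *technical
duplicates* (identical slices re-saved or re-compressed under different
names) that leak across train/validation boundaries and inflate
accuracy, and *uncontrolled capacity* when architectures of different
sizes are compared. The package addresses both: a dedup-aware curation
front end, and an exact trainable-parameter budget enforced by a
forward-inert pad.

## Curation

`curate()` discovers the class root (the root itself, then `Training/`
and `Testing/` containers, then first-level children, each accepted when
it has at least two subdirectories), canonicalizes folder names through
a synonym table after lowercasing and separator stripping, and removes
near-duplicates per class before a seeded stratified split.

The duplicate detector is the classic average hash: the image is
converted to BT.601 luma, resampled to an 8×8 thumbnail, and thresholded
at the thumbnail mean with a *strict* inequality, so a constant image
hashes to all-zero bits. The 64 bits are packed row-major, MSB-first,
and digested with SHA-1; only exact key collisions inside a class are
treated as duplicates (no Hamming-distance search). Pinned numerical
choices, so keys are portable across machines:

* thumbnail resampling is bilinear at output-pixel centers (half-pixel
  convention, no corner alignment);
* grayscale is `0.299 R + 0.587 G + 0.114 B`;
* records are visited in lexicographically sorted path order, removing
  any filesystem-order nondeterminism — the first record per key wins.

The split shuffles each class with a seeded generator and sends the
first `round(f·n)` files (round half up, floor of one when `n ≥ 2`) to
validation. A class with a single record trains with a warning; an empty
class errors. A predefined `Testing/` container is detected by name
(case-insensitive), deduplicated within itself, and never re-split.
Dedup runs per class *within* each container, so train/test dedup
boundaries mirror the original container boundaries.

## Augmentation and the curriculum

Training-time augmentation composes, in order: a sampled affine warp
(rotation ±10°, shifts up to 8% of each side, shear up to 6°, zoom
0.8–1.2) with bilinear sampling and zero fill, an optional horizontal
flip, and brightness scaling in [0.92, 1.10]. CLAHE, when its gate
fires, operates on the L channel of CIE-LAB only (clip limit 2, 8×8
tiles). The CLAHE implementation uses midpoint-CDF tile mappings with
bilinear interpolation between tile centers; the midpoint form makes a
uniform image a fixed point up to quantization, which the test suite
checks at 1/255.

Random erasing draws an area fraction `u ~ Unif(0.02, 0.15)` and aspect
`r ~ Unif(0.3, 3.3)`, giving a rectangle of sides `⌊√(S·r)⌋ × ⌊√(S/r)⌋`
with `S = u·H·W`, placed uniformly among fully contained positions and
filled with U(0,1) noise; degenerate draws are resampled up to ten
times, then the image is returned unchanged. Placement among *contained*
positions (clipping only when a side exceeds the image) keeps the
realized erased area equal to the sampled one.

MixUp and CutMix operate on index-aligned batch pairs built from two
independently seeded permutations, one mixing weight per batch. MixUp
draws `λ ~ Beta(0.3, 0.3)`; CutMix pastes one rectangle (same area/
aspect law as erasing, center uniform) and always recomputes
`λ = retained pixels / (H·W)` from the realized rectangle, computed as a
single ratio so it is bit-identical to a pixel-count oracle. When both
gates could fire, the two are mutually exclusive per batch: one draw
decides whether *any* mixing happens (probability `p_mix + p_cut`), and
the variant is chosen in proportion to the two probabilities.

The curriculum is a piecewise-constant epoch schedule with half-open
intervals and breakpoints at epochs 2, 10 and 36:

| epochs | MixUp | CutMix | erase | CLAHE | smoothing |
|---|---|---|---|---|---|
| [0, 2) | 0 | 0 | 0 | 0 | 0.05 |
| [2, 10) | 0.15 | 0.15 | 0.08 | 0.06 | 0.05 |
| [10, 36) | 0.25 | 0.25 | 0.12 | 0.08 | 0.03 |
| [36, ∞) | 0 | 0 | 0 | 0 | 0 |

The first row's published form lists only four numbers against five
names; it is resolved here as *all perturbations off, smoothing 0.05*,
consistent with the design intent of mild early training.

## Architecture

`build_model(arch_config())` assembles: Gaussian input noise (sd 0.05,
training only) → two Conv3×3–BN–GELU stem layers at widths (32, 64) →
2×2 max pool → three separable blocks at widths (128, 320, 640), each
depthwise 3×3 → pointwise 1×1 → batch norm → GELU →
squeeze-and-excitation gate → 7×7 spatial gate, with a 2×2 pool after
each block → global average pooling → Dense(256)+GELU+Dropout(0.35) →
softmax. Convolutions carry no bias (batch norm follows); GELU uses the
tanh approximation.

Decisions worth recording:

* **SE bottleneck.** The excitation MLP is specified with
  `W₁ ∈ ℝ^{r×C}`, `r = 16` — a *fixed* 16-unit bottleneck rather than
  the conventional `C/16` reduction. The package implements the printed
  form by default (`se_mode = "fixed"`) and offers `"ratio"` as a
  config switch.
* **Stem widths** are not recoverable from the published description;
  (32, 64) keeps the realized base count (481,597) under the budget
  with a conventional doubling progression. The realized count is
  always reported by `model_summary()`.
* **Block order** follows the narrative order (attention after the
  normalized, activated separable pair); both gates multiply by values
  strictly inside (0, 1), so they only attenuate.
* **One pool after the two stem convs**, per the printed pipeline.
* **MAC accounting** counts conv and dense multiply-accumulates only
  (BN, activations and gates are ignored, as is conventional); it is a
  diagnostic, not a comparison surface, because counting conventions
  for attention vary.

The capacity pad appends a trainable vector `p` whose only use in the
forward pass is the term `0 · Σⱼ pⱼ`: outputs are bit-identical to the
unpadded model and `∂L/∂p = 0` exactly. After padding,
`count_trainables()` equals the budget `P* = 1,461,587` exactly
(5.58 MB at four bytes per parameter). AdamW's decoupled decay does
shrink the pad over training; this is harmless by construction since the
pad never enters the forward function.

All layers and gradients are implemented in R over BLAS: the
architecture and training recipe are the core of the package, and
keeping them free of deep-learning-framework dependencies lets the
whole pipeline run and verify on a plain R installation. The backward
pass of every layer is validated against central finite differences in
`test-model.R`; the analytic gradient is the convergence point of the
numerical one as the step shrinks.

## Optimization

AdamW (β₁ = 0.9, β₂ = 0.999, ε = 1e-7 — framework-conventional values,
pinned in `train_config()`) with decoupled weight decay 1e-4, applied
after clipping the *global* gradient norm at 1.0. The learning rate is
`η₀·t/T_w` during warmup and
`η_min + ½(η₀−η_min)(1 + cos(π(t−T_w)/T_d))` afterwards, so it is
continuous at `T_w`, strictly decreasing after it, `η₀ = 3e-4` at the
end of warmup and `η_min = 1e-6` at the last step. The published
formula multiplies the warmup and cosine factors and omits the ½; taken
literally it would emit `2η₀ − η_min` at the end of warmup,
contradicting the stated base rate, so the standard half-amplitude form
is used deliberately.

The schedule horizon is `total_steps = max_epochs × ⌊n_train/batch⌋`,
fixed in advance even when early stopping fires sooner. Early stopping
monitors *validation accuracy* (no TTA during training); after
`patience` epochs without improvement the best epoch's weights are
restored. Sample weights under mixed labels are the label-mass-weighted
class weights `Σ_k y_k w_k` of the *mixed, pre-smoothing* label, and the
batch loss is the plain mean of weighted per-sample cross-entropies
(with `w_k = N/(K n_k)` the dataset-mean weight is 1, so this matches
the normalized weighted mean in expectation).

## Evaluation

`tta_predict()` averages softmax outputs over exactly five
deterministic views: identity, horizontal flip, rotations of ±8°
(bilinear, zero fill outside the frame), and gamma correction
`x^0.9` — the "mild" gamma magnitude is not specified anywhere, so 0.9
is pinned in `tta_config()` and overridable. ECE uses 10 equal-width
right-closed confidence bins (the bin count is likewise unspecified in
the source material; 10 is the common default). The Brier score is the
full sum-over-classes form, which ranges over [0, 2]; the /K variant
differs by a constant factor and is *not* used. Precision/recall
zero-divisions yield 0 with a `zero_division` flag rather than NaN.

## The phantom generator

`make_phantom()` renders a skull ellipse (per-phantom random semi-axes
and center, emulating head-size variation), smooth interior texture
(bilinear-upsampled coarse noise), a class-conditional lesion, and
additive Gaussian noise (sd 0.02):

* glioma — large irregular blob (radius ≈ 0.15 of the image, angularly
  modulated boundary), laterally offset into one hemisphere;
* meningioma — medium disc (radius 0.085) attached to the inner skull
  rim at a random angle;
* pituitary — small midline-inferior blob (radius 0.045);
* no tumor — no lesion.

Classes are separable by lesion geometry (size and shape, which survive
global average pooling), not intensity alone, so the attention gates
have spatial signal to exploit. `make_corpus()` writes
`Training/<class>/img_XXXX.png` trees (PNG, so injected duplicates are
byte-identical; lossy formats would break that), optional synonym folder
names and `Testing/` containers, and a ground-truth JSON for test
assertions. Duplicate copies are named so they sort *after* their
source, matching the keep-first dedup rule. Because distinct phantoms
must carry distinct hash keys for the ground truth to be exact, the
generator redraws an image on the rare 8×8-thumbnail collision.

What the phantoms do *not* emulate: MRI physics (bias fields, k-space
artifacts), anatomical detail, inter-scanner variation, patient-level
correlation between slices. Passing the end-to-end smoke test therefore
demonstrates that the pipeline's mechanics work and the architecture can
learn geometric class structure — not that headline accuracies on real
MRI data are reproduced. Those require the external dataset and
full-scale training, which the pipeline supports but the test suite does
not attempt.

## Problem sizes used by the test suite

The suite runs the full-scale model only for capacity accounting (no
forward pass). Learning dynamics are exercised on a reduced 64×64
variant (stem 8/16, blocks 16/32/64, 64-unit head, ~13k parameters)
chosen so a complete curate → train → evaluate cycle on 200 phantoms
finishes in minutes on one CPU core. Two training probes are defined:

* an **optimization-capacity probe** — 40 phantoms, 30 epochs,
  stochastic regularizers (dropout, input noise, augmentation,
  curriculum) disabled, base rate 3e-3 — which must reach training
  accuracy 1.0; regularizers are off because the probe tests the
  optimizer and architecture, not generalization;
* an **end-to-end smoke run** — 180/20/52 phantom split, 15 epochs with
  the full augmentation curriculum, base rate 3e-3 — which must reach
  held-out accuracy ≥ 0.9 under TTA.

The base rate for these desk-scale runs is scaled up from the full
recipe's 3e-4 because the runs take roughly a tenth of the optimizer
steps; the schedule shape (10% warmup, cosine to 1e-6) is unchanged.
Three seeds are allowed for the stochastic smoke runs.

## Known limitations

* File-level splitting only: with no patient identifiers, slices of one
  patient can in principle straddle splits; exact-key dedup mitigates
  but cannot eliminate this.
* The hash is intentionally strict — only identical 8×8 threshold
  patterns collide; visually near-identical images with different
  patterns survive.
* Mixed precision is not implemented: all computation is float64 R,
  which is the determinism-friendly setting for CPU verification.
* Training at 256×256 full scale is supported but slow in this
  implementation; its intended desk-scale use is verification,
  curation, and architecture accounting.
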