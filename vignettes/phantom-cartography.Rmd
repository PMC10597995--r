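---
title: "Saliency cartography for mandibular retrognathia: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saliency cartography for mandibular retrognathia: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem and the approach

Class II malocclusion by mandibular retrognathia (C2Rm) is diagnosed on
lateral cephalometric radiographs from three Steiner angles: SNA and SNB
(anteroposterior projection of maxilla and mandible against the
sella–nasion line) and their difference ANB = SNA − SNB. Landmark-based
analyses see only the structures a practitioner chose to measure.
`cephcam` implements the alternative: train a convolutional network to
separate physiological (Class I) from retrognathic (Class II) skulls,
then ask the network *where it looked* via class-activation saliency
maps, average those maps over the cohort into a **global activation
map** that suppresses inter-individual variability, stratify it by
severity, and quantify delineated regions with two scalar metrics.

The clinical images behind this design are not public, so the package
ships a first-class synthetic phantom generator that reproduces the
*causal structure* the analysis assumes — a class-separating mandible
displacement plus severity-scaled secondary effects planted in named
regions — with exact ground truth (landmarks, masks, labels). Every
downstream stage is tested against that ground truth.

## Pipeline

1. **Cephalometrics.** `compute_angles()` measures SNA/SNB as unsigned
   ray angles at the nasion and defines ANB through the identity
   SNA − SNB. Labeling (`classify_angles()`) applies, in precedence
   order: borderline exclusion (−1 ≤ ANB ≤ 1), Class II (ANB > 4 and
   SNB < 76), Class I (ANB in [0,5], SNA in [79,85], SNB < 77),
   otherwise `excluded_other`. The exclusion-first order is deliberate:
   borderline cases overlap the Class I window, and silently keeping
   them would blur the class boundary. Cases with ANB > 5 and
   76 ≤ SNB < 77 satisfy neither class rule; we refuse to force a label
   and route them to `excluded_other`. Severity bins are half-open,
   lower-closed ([6,7), [7,8), [8,9), [9,∞)); the edges are configurable
   because clinical gradings sometimes add a [4.5,6) level.
2. **Preprocessing.** Bilinear resize to a square target (default 256,
   desk default 128), min–max normalization to [0,1] (a constant image
   maps to zeros — the only deterministic choice that avoids a division
   by zero), then Sobel gradient magnitude (replicate boundary,
   renormalized). Sobel output *replaces* the intensity image by
   default; a flag keeps the raw image instead. Train-time augmentation
   draws a rotation from multiples of 10° within ±30°, a zoom within
   ±3% and translations within ±3% of the image side, composed into one
   bilinear warp about the pixel at (size/2, size/2) with zero fill.
   The ±30° rotation bound and the 3% shift are package defaults chosen
   to mirror the 3% zoom convention.
3. **Classifier.** Seven conv–batch-norm–ReLU blocks (desk widths
   8-8-16-16-32-32-32, 3×3 kernels, 2×2 max pooling after the first
   three blocks), global average pooling, dropout 0.5, fully connected
   softmax head. Training is Adam with lr = 1e-3 decaying ×0.95 per 100
   epochs, cross-entropy, stratified 5-fold splits whose test folds
   hold exactly ⌊n/k⌋ per class, with remainder samples always assigned
   to training (so 1317 subjects split 1054/263 and 1377 split
   1102/275). Clinical-scale runs of this kind of model are much wider
   (hundreds of thousands of parameters), but the exact wide
   architecture is not the point here: the architecture is
   config-driven and the parameter count is reported, not chased.
   After the last epoch the
   batch-norm inference statistics are recomputed with frozen weights
   (a "precise BN" pass): the training-time moving average lags the
   rapidly moving weights badly enough in a seven-layer stack to
   corrupt inference-mode predictions, and recalibration removes that
   bias deterministically.
4. **Saliency.** The default method follows the gradient-weighted
   equations: Gi = ∂Sc/∂Ai on the last convolutional layer's
   activations, Mi = Gi × ReLU(Ai), per-channel weights
   α = GlobalAvgPool(Mi), S = Σ α·Mi, then ReLU, bilinear upsampling to
   input resolution, and per-map min–max normalization. These equations
   are gradient-weighted (Grad-CAM family), so the default method flag
   is `"grad-cam"`; canonical gradient-free Score-CAM
   (`scorecam_map()`) is available behind a flag for comparison, since
   the two families are often used interchangeably in this literature.
   Sc defaults to the
   pre-softmax logit of the target class (the CAM-literature
   convention); the softmax probability is available via
   `score = "prob"`. The final ReLU and the per-map normalization make
   the 0.3 threshold comparable across images. α is one scalar per
   channel (spatial mean), so that it weighs the significance of each
   channel as a single scalar. Maps are generated for images classified
   positive (predicted Class II) by default; a switch restricts to true
   labels instead, since either reading of "positive" is defensible.
5. **Cartography.** The global activation map is the pixelwise mean
   G = (1/N) Σ Si of aligned maps, displayed over an averaged-skull
   backdrop (pixelwise mean image). Phantom cohorts are generated
   pre-aligned (rigid jitter defaults to zero), so alignment defaults
   to a pass-through; `mode = "rigid"` estimates a translation (plus an
   optional small-angle rotation search) by FFT cross-correlation on
   the source images and drops maps whose correlation falls below a
   floor. Thresholding keeps pixels **≥** 0.3 ("below … eliminated"
   leaves the boundary in). The *class score* of a region is the mean
   of its suprathreshold pixels (0 with a flag if none survive — kept
   finite so downstream tables stay rectangular; all-pixel averaging is
   available for sensitivity analysis), and the *hot surface* is the
   fraction of region pixels at or above the threshold. Per-subject
   metrics (each individual map against the consensus region masks)
   feed the ANOVA, which needs subject-level replication; per-bin
   global-map metrics are also available for map-level summaries.
6. **Statistics.** One mixed (split-plot) two-way ANOVA per metric:
   severity bin between subjects, anatomical structure within subjects,
   the bin effect tested against the subject-within-bin stratum.
   Degrees of freedom are always computed from the data, never assumed
   from a nominal design. Sphericity corrections are not applied by
   default (the within factor has few levels and the phantom noise is
   exchangeable); post hoc comparisons are Welch t-tests on
   per-subject means over all bin pairs with Bonferroni adjustment
   min(1, p·m), m = number of pairs. Constant tables report F = 0,
   p = 1 with a flag rather than NaN.

## The phantom generator

`generate_sample()` draws parametric structures on a dark background:
a cranial vault ellipse band, a cranial base band from the sella
towards the nasion, a frontal sinus blob, four vertebral bodies and the
jaws (maxilla blob, mandibular body, chin). Severity maps affinely to
the angles — SNA fixed at 80.5°, SNB = 76.5° − severity, hence
ANB = 4° + severity — so severity 0 is Class I, severity > 0.5 crosses
the Class II rule, and severities 2–6.5 cover the four ANB bins
exactly. The B-point (and with it the mandibular contour) retrudes
geometrically with severity; the four secondary regions gain intensity
(and, for the parietal band and sinus, thickness) linearly in severity
× effect multiplier. Additive Gaussian noise (sd 0.03, clipped to
[0,1]) makes single-image saliency noisy while population averages
stay stable. Class I severities are drawn U(0, 0.4); Class II draws
ANB U(6, 10.5), matching the binned severity range of the study
design.

What the phantom does *not* emulate: anatomical texture, projective
geometry, age/sex/ethnicity variation, device characteristics, or
correlated anatomical covariation. A passing pipeline therefore
demonstrates that the method recovers *planted, causally separable*
signal; it says nothing about effect sizes in clinical radiographs.

## Desk-scale study conditions

The end-to-end study (`run_phantom_study()`, also what
`scripts/acceptance.R` runs) uses 400 phantoms per class at 128×128,
trains 30 epochs with batch 32 on the first 80/20 cross-validation
fold, explains the predicted-positive test images, and then evaluates
severity response on five independently seeded cohorts of 20 subjects
per bin, reusing the single trained classifier — the severity question
is about the saliency response to planted effects, and retraining per
cohort would only add classifier variance. Clinical-scale settings
(256×256, 1000 epochs, batch 100) remain reachable through
configuration. Region recovery is scored as the IoU between the
top-decile saliency pixels and the union of planted masks, against a
permutation baseline of random circular placements of the same mask
area.

## Numerical choices and degenerate inputs

- Min–max of a constant array returns zeros everywhere it appears
  (normalization, saliency maps, backdrops).
- Bin edges are guarded against float round-off by rounding recovered
  ANB to 1e-6 degrees before binning (the landmark-consistency
  contract is 0.1°).
- Max-pool ties resolve to the first maximum in column-major order.
- Out-of-frame pixels after any rigid transform are zero-filled;
  bilinear sampling renormalizes partial corner weights against the
  fill value.
- The master seed drives separate derived streams for cohort
  generation, fold assignment, weight initialization and the
  training-time shuffle/augmentation/dropout draws, so every stage is
  independently reproducible.
- Conv biases sit directly before batch normalization and therefore
  receive (correctly) zero gradient; they are kept for architectural
  generality.

## Known limitations

- The CNN is a desk-scale re-implementation (tens of thousands of
  parameters); it is not intended to reproduce clinical accuracy
  figures, which were measured on a private cohort at GPU scale.
- Rigid alignment estimates integer-pixel translations (plus optional
  gridded rotations); there is no subpixel or non-rigid registration.
- The mixed ANOVA assumes a balanced, complete within-subject design
  and does not apply sphericity corrections by default
  (Greenhouse–Geisser is intentionally out of scope; the within factor
  has only four levels here).
- Score-CAM weights use a zero-image baseline; other baselines are not
  implemented.

## A worked micro-example

```{r example}
library(cephcam)

co <- generate_cohort(c(classI = 40, classII = 40),
                      phantom_params(image_size = 128), seed = 1)
pc <- preproc_config(target_size = 128)
imgs <- lapply(co$samples, function(s) preprocess_image(s$image, pc))

model <- build_model(model_config(input_size = 128), seed = 1)
model <- train_classifier(model, imgs, co$manifest$label,
                          train_config(epochs = 25, seed = 1),
                          augment_config = pc)

maps <- explain_cohort(model, setNames(imgs, co$manifest$id))
G <- global_map(lapply(maps, unclass), backdrop = averaged_skull(imgs))
masks <- consensus_masks(co$samples)
roi <- roi_metrics(lapply(maps, unclass), masks,
                   bins = co$manifest$bin[match(names(maps),
                                                co$manifest$id)])
head(roi)
```
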