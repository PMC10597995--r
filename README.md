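# cephcam

Interpretable-CNN saliency cartography for mandibular retrognathia on
lateral skull radiographs.

## What this package is for

Class II malocclusion by mandibular retrognathia (C2Rm) is diagnosed
from three Steiner cephalometric angles measured at the nasion (N)
against the sella (S), maxillary A-point and mandibular B-point:

- **SNA**, **SNB** — anteroposterior projection of maxilla and mandible,
- **ANB = SNA − SNB** — their sagittal discrepancy; Class II
  retrognathia is ANB > 4° with SNB < 76°, graded by ANB into severity
  bins [6°,7°), [7°,8°), [8°,9°), [9°,∞).

Angle-based analyses only see the jaws. `cephcam` implements a
whole-skull alternative for researchers in orthodontics and
morphometrics: train a small CNN to separate physiological (Class I)
from retrognathic (Class II) radiographs, extract per-image
class-activation saliency maps from its last convolutional layer

&nbsp;&nbsp;G<sub>i</sub> = ∂S<sub>c</sub>/∂A<sub>i</sub>,&nbsp;
M<sub>i</sub> = G<sub>i</sub> × ReLU(A<sub>i</sub>),&nbsp;
α = GlobalAvgPool(M<sub>i</sub>),&nbsp;
S = Σ α·M<sub>i</sub>,

average the aligned per-image maps into a **global activation map**
G = (1/N) Σ S<sub>i</sub> that suppresses inter-individual variability,
stratify it by ANB severity bin, and quantify delineated bone regions
with two metrics over the suprathreshold (≥ 0.3) pixels: the **class
score** (mean suprathreshold activation in the region) and the **hot
surface** (fraction of region pixels above threshold). Two mixed
two-way ANOVAs (ANB bin between subjects, anatomical structure within
subjects, Bonferroni post hoc) test how the metrics evolve with
severity.

Because clinical cephalograms of this kind are not publicly available,
the package includes a first-class **synthetic phantom generator**:
parametric skulls whose mandible retrudes with a controllable severity
(ANB = 4° + severity exactly) and whose cranial base, frontal sinus,
parietal band and vertebrae carry severity-scaled planted effects, with
ground-truth landmarks, masks and labels. The whole pipeline is
developed and tested against that ground truth; a gradient-free
Score-CAM variant is included for comparison.

## Worked example

```r
library(cephcam)

# 1. synthetic cohort with planted ground truth
cohort <- generate_cohort(c(classI = 60, classII = 60),
                          phantom_params(image_size = 128), seed = 42)

# 2. standardize: resize -> [0,1] normalize -> Sobel
pc   <- preproc_config(target_size = 128)
imgs <- lapply(cohort$samples, function(s) preprocess_image(s$image, pc))

# 3. train on the first 80/20 cross-validation fold
folds <- make_cv_splits(cohort$manifest$label, k = 5, seed = 1)
tr <- folds[[1]]$train; te <- folds[[1]]$test
model <- build_model(model_config(input_size = 128), seed = 1)
model
#> ceph_cnn: 7 conv blocks ( 8-8-16-16-32-32-32 channels ), 27642 parameters; untrained
model <- train_classifier(model, imgs[tr], cohort$manifest$label[tr],
                          train_config(epochs = 25, seed = 1),
                          augment_config = pc)
evaluate_classifier(model, imgs[te], cohort$manifest$label[te])$accuracy
#> [1] 1

# 4. saliency maps for predicted Class II images -> global activation map
maps <- explain_cohort(model, setNames(imgs[te], cohort$manifest$id[te]))
length(maps)
#> [1] 12
G <- global_map(lapply(maps, unclass), backdrop = averaged_skull(imgs[te]))
G
#> global_map ( all ): mean of 12 maps, 128 x 128

# 5. ROI quantification against the planted ground-truth regions
masks <- consensus_masks(cohort$samples[te],
                         regions = c("cranial_base", "frontal_sinus",
                                     "parietal", "vertebrae"))
roi_metrics(list(global = G$G), masks)[, c("region", "class_score",
                                           "hot_surface")]
#>          region class_score hot_surface
#> 1  cranial_base   0.6918704   0.4243697
#> 2 frontal_sinus   0.0000000   0.0000000
#> 3      parietal   0.7426649   0.9840764
#> 4     vertebrae   0.5670671   0.7523810
```

The classifier separates the phantom classes perfectly on the held-out
fold, and the global activation map concentrates on planted regions:
here the parietal band is almost entirely suprathreshold (hot surface
0.98) with a class score of 0.74, while the frontal sinus did not cross
the 0.3 threshold in this small cohort (score 0, flagged). On the
full-size study (400 per class, severity cohorts over five seeds) both
metrics rise monotonically across the four ANB bins — see below.

Severity-stratified maps and the statistical report follow the same
pattern with `severity_maps()`, `mixed_anova()` and `write_report()`;
`run_phantom_study()` wires the whole pipeline together. A thin CLI
over the same functions ships in `inst/cli/cephcam.R`
(`generate` / `train` / `explain` / `report`).

## Package layout

| Module | Contents |
|---|---|
| `R/phantom.R` | synthetic cephalogram generator, cohort writer (PNG + CSV manifest) |
| `R/cephalometrics.R` | SNA/SNB/ANB geometry, labeling rules, severity bins, selection pipeline |
| `R/preprocess.R` | resize / normalize / Sobel, seeded rigid+zoom augmentation |
| `R/classifier.R`, `R/nn.R`, `src/convnet.cpp` | configurable conv–BN–ReLU CNN, Adam training, stratified k-fold CV |
| `R/saliency.R` | gradient-weighted activation maps, Score-CAM variant, cohort explanation |
| `R/cartography.R` | map alignment, global/severity maps, threshold, class score, hot surface, IoU baselines |
| `R/stats_report.R` | mixed two-way ANOVA, Bonferroni post hoc, report bundle |
| `R/study.R` | `run_phantom_study()` end-to-end driver |
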