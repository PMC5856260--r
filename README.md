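# fibroquant

Fully automated histomorphometric quantification of lung fibrosis on
Masson's-trichrome whole-slide images, for preclinical researchers running
bleomycin studies in rodents who need reproducible, rater-independent
readouts instead of semi-quantitative Ashcroft/Hübner scoring.

The pipeline separates the two histological hallmarks of pulmonary fibrosis
with two SVM pixel classifiers applied at different magnifications of the
slide pyramid:

1. **Low magnification** (the pyramid level nearest one megapixel): a 4-class
   model — `background`, `fibrotic_mass`, `alveolar_tissue`, `bronchus`
   (including its constitutive peri-bronchial collagen) — produces the
   *exclusion map*. From it:
   - **% fibrotic masses** `= 100 · mass / (mass + alveolar_tissue)`
     (bronchi and background excluded from the normalization), and
   - the alveolar **region of interest (ROI)** for stage two.
2. **Full resolution**, inside the ROI only, tiled into 512×512 tiles with a
   window halo and aggregated map-reduce style: a 3-class model —
   `collagen`, `lung_tissue`, `background` — yields
   - **% alveolar collagen** `= 100 · collagen / (collagen + lung_tissue)`
     (alveolar air excluded from the denominator), and
   - **% total collagen** (alveolar collagen plus fibrotic-mass area over
     parenchymal tissue).

Every pixel is described by per-channel features over a square
"structure-size" window: the pixel's own intensity, window mean / min / max /
variance, and the **edge factor**
`EF(p) = (1/(|W|−1)) · Σ_{p'∈W} (p'−p)²`. The SVM is an RBF-kernel machine
(random Fourier features + dual coordinate descent, implemented in this
package) trained on pixels sampled from polygon annotations — 40,000 random
pixels over every class and image by default — and evaluated by stratified
10-fold cross-validation. Group statistics use the Mann-Whitney U test
(exact for small tie-free samples) with means ± SEM.

Because scanned slides are large and not redistributable, the package ships
a **synthetic slide generator**: trichrome-like pyramids (lacy alveolar
septa, dense fibrotic masses, bronchi with collagen collars, stain hue and
intensity drift) with exact per-pixel ground truth, so the whole pipeline is
testable end to end. See the methods vignette
(`vignettes/fibroquant-methods.Rmd`) for the model, its assumptions and the
design decisions.

## Worked example

```r
library(fibroquant)

# a diseased synthetic slide (30% fibrotic masses, 6% septal collagen)
slide <- generate_slide(synthetic_slide_params(
  width_px = 1280L, height_px = 1280L,
  fibrotic_mass_fraction = 0.30, alveolar_collagen_fraction = 0.06,
  n_bronchi = 3L, seed = 11L))

# train both models on a stain-matched fixture slide (simulated rater)
fix <- generate_slide(synthetic_slide_params(
  width_px = 1280L, height_px = 1280L, fibrotic_mass_fraction = 0.25,
  alveolar_collagen_fraction = 0.06, n_bronchi = 3L, seed = 21L))
low <- select_low_mag_level(fix$pyramid)
ann_low  <- generate_annotations(fix$gt, 10L, seed = 31L, model = "low",
                                 scale = low$scale)
ann_high <- generate_annotations(fix$gt, 10L, seed = 61L, model = "high")
ts_low <- build_training_set(list(slide = low$image), ann_low,
                             feature_config(15L), 12000L, seed = 5L)
clf_low  <- train_classifier(ts_low)
clf_high <- train_classifier(build_training_set(
  list(slide = fix$pyramid$levels[[1]]), ann_high, feature_config(5L),
  12000L, seed = 6L))

quantify_slide(slide$pyramid, clf_low, clf_high)
#> <fq_slide_quantification>
#>   fibrotic masses:    25.07 %
#>   alveolar collagen:   6.66 %
#>   total collagen:     44.87 %
#>   ROI: 638968 px | QC flagged: FALSE
100 * slide$gt$mass_fraction   # ground truth: 30.19
```

The mass readout tracks the generated truth (25.1% vs 30.2% with this
single-fixture model; training across the stain-drift range, as the test
suite does, brings the mean absolute error to ~3 points over a 5-45% sweep).
The alveolar collagen readout recovers the true septal collagen fraction
closely when training and test stains match (6.66% vs 6.0% here) but is
biased upward under stain drift at this desk scale — thin synthetic septa
put many pixels within one feature-window radius of an air boundary; see
the vignette's scale discussion. It remains monotone in the true burden
(Spearman 0.96 in the acceptance sweep).

Cross-validating the low-magnification model:

```r
cross_validate(ts_low, k = 10L, seed = 1L)
#> <fq_cv_report> 10-fold CV: mean accuracy 0.9952 (folds 0.9917-0.9967)
```

## Batch CLI

```sh
inst/cli/fibroquant synth    study.json    # synthetic study -> TIFFs + metadata
inst/cli/fibroquant train    models.json   # annotations -> model_low/high.json
inst/cli/fibroquant cv       models.json   # stratified 10-fold CV, JSON report
inst/cli/fibroquant quantify batch.json    # slides -> study_table.csv
inst/cli/fibroquant stats    stats.json    # group comparisons (Mann-Whitney)
```

Exit codes: 0 ok, 2 config error, 3 partial failure. All configs are JSON;
all seeds live in the config.

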