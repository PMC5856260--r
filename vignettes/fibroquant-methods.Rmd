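---
title: "Methods: automated histomorphometry of lung fibrosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated histomorphometry of lung fibrosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the two readouts

Bleomycin-induced pulmonary fibrosis in rodents is conventionally scored by a
pathologist on Masson's trichrome sections (Ashcroft/Hübner scales), which is
semi-quantitative and rater-dependent. fibroquant implements a fully automated
two-stage pixel-classification pipeline over whole-slide image pyramids that
separates the two histological hallmarks of the disease:

1. **Percent fibrotic masses** — dense remodelled regions replacing alveolar
   architecture, detected on a *low-magnification* view (around one
   megapixel) where a large feature window captures regional texture. The
   4-class model labels every pixel `background`, `fibrotic_mass`,
   `alveolar_tissue` or `bronchus` (the bronchus class includes the
   constitutive peri-bronchial collagen). The readout is
   `100 * mass / (mass + alveolar_tissue)`.
2. **Percent alveolar collagen** — early septal collagen deposition, detected
   at *full resolution* inside the alveolar region of interest (ROI) only.
   The 3-class model labels ROI pixels `collagen`, `lung_tissue` or
   `background`; the readout is `100 * collagen / (collagen + lung_tissue)`.

The low-magnification map is the "exclusion map": the ROI is the alveolar
tissue, so bronchi (whose collagen is normal anatomy, not disease), fibrotic
masses and background never contribute to the collagen readout. A third,
derived readout — percent total collagen — combines alveolar collagen with the
fibrotic-mass area (see *Numerical choices*).

## The pixel classifier

Every pixel is described per colour channel by its own intensity (the
single-pixel feature) plus window statistics over a square window of edge
length `structure_size` centred on it: mean, min, max, variance, and the
**edge factor**

$$\mathrm{EF}(p) = \frac{1}{|W|-1}\sum_{p' \in W}(p'-p)^2,$$

a local-contrast descriptor (zero on flat regions, large at structure
boundaries). Windows are clipped at image borders and all divisors use the
actual $|W|$; the centre pixel belongs to $W$ (its term is zero). With RGB
input the default feature vector has 18 entries. The single-pixel intensity
matters: without it, any pixel whose window straddles a boundary is
undecidable from window statistics alone.

Classification is a soft-margin RBF-kernel SVM, trained on pixels sampled
from rater annotations. Because no SVM solver is available in the supported
dependency set — and because the classifier is the core of the package — the
SVM is implemented here as:

* standardization of each feature (constants stored in the model);
* a random Fourier feature (RFF) expansion of the RBF kernel
  $k(x,y)=\exp(-\gamma\|x-y\|^2)$ with $D = 256$ features,
  $z(x)=\sqrt{2/D}\,\cos(\Omega^\top x + b)$, $\Omega \sim N(0, 2\gamma I)$,
  $b \sim U(0, 2\pi)$;
* one linear SVM per class (one-vs-rest), solved by dual coordinate descent
  (L1 hinge loss, $C=1$), with inverse-frequency class weights on the
  positive class (switchable); prediction is winner-take-all over the
  one-vs-rest margins, ties broken toward the lowest class index.

Defaults: $\gamma = 1/n_\mathrm{features}$, $C = 1$ (neither is stated by the
method's sources; both are config keys). The RFF approximation keeps training
on tens of thousands of pixels and prediction on megapixel rasters linear in
the pixel count; with the well-separated trichrome classes its approximation
error is far below the decision margins. All stochastic components (RFF draw,
solver order, sampling, fold assignment) derive from a single seed; repeated
runs are bit-identical.

**Training sets** pool all annotated pixels over every class and image and
draw 40,000 pixels (default) uniformly without replacement — deliberately
*not* stratified, matching random picking over the pooled annotations; the
inverse-frequency class weights in the SVM compensate rare classes instead.
Model quality is estimated by stratified 10-fold cross-validation (per-class
fold sizes differ by at most one; each sample is tested exactly once).

## The synthetic slide generator

Scanned rat slides are not distributable, so the generator produces
trichrome-like pyramids with exact ground truth. It is a stated world, not a
tuning dial: its defaults are fixed and tests must live with them.

* **Alveolar texture**: a Voronoi ridge lattice — thin red septa
  (`septum_px = 12` at full resolution) around white airspaces
  (`alveolus_px = 42` mean diameter). Micrographs motivate the thin-wall /
  lumen geometry; the lattice is the cheapest texture with that property.
* **Fibrotic masses**: random ellipses (radius 12–20% of the image dimension)
  placed until the realized mass fraction of parenchyma is within ±2 points
  of the requested value. Internally cell-rich (red) with fine collagen
  strands (~8 px patches, 40% of mass area) — masses are fibroblast- and
  cell-dominated.
* **Bronchi**: white lumen (r = 10 px), red wall (to 32 px), blue collagen
  collar (to 80 px). The collar exists precisely so that its exclusion from
  the collagen ROI is testable.
* **Material shades**: airway smooth muscle and peri-bronchial collagen are
  rendered darker (gain 0.65) and fibrotic-mass material slightly darker
  (0.9) than alveolar walls — as in real trichrome, where mature compact
  collagen and muscle stain more densely. At desk scale these shades carry
  part of the discrimination burden that sheer structure size carries on
  real gigapixel slides.
* **Intensity texture**: a mild spatially correlated brightness field
  overlays all materials (staining inhomogeneity, section thickness). This
  is load-bearing: in a flat-shaded world every pure training window has
  identical variance, the variance/edge features are degenerate, and
  mixed-boundary windows at prediction time become extreme out-of-range
  points whose one-vs-rest scores are effectively arbitrary.
* **Alveolar collagen**: a clustered fraction of septal pixels is painted
  collagen in chunky contiguous segments; the realized fraction is computed
  from the emitted maps and recorded as ground truth.
* **Stain drift**: global HSV hue rotation (±15°) and scalar channel gain
  (0.8–1.2) per slide, plus a smooth within-slide gradient (hue ±3°,
  intensity ±5% — sections are never uniformly stained) and per-channel
  Gaussian noise (SD 8). This reproduces, only qualitatively, the
  reddish/orange/bluish and blue-to-grey drift of historical staining
  batches. The within-slide gradient also matters statistically: it makes
  every training fixture cover a neighbourhood of the drift space instead of
  a single point, which stabilizes the collagen readout on slides whose
  drift falls between fixtures. Drift never alters the ground truth.
* **Pyramid**: 2× mean pooling down to ≤1024 px; half-open coordinates,
  origin top-left, level 1 = full resolution.

The ground truth carries two rasters: the 5-label `label_map`
(background / fibrotic_mass / alveolar_tissue / bronchus / alveolar_collagen,
with *region* semantics — alveolar airspaces are `alveolar_tissue`), standing
in for the pathologist's judgement, and a `material_map`
(background / tissue / collagen) from which rendering derives and which
defines high-magnification truth. Both are needed because the five region
labels alone cannot distinguish septal tissue from alveolar air.

What the generator does **not** emulate: nuclei, vessels, scanner artefacts
(blur, stitching), photorealistic stain chemistry, lobe-specific anatomy. A
green pipeline test therefore establishes that the machinery — features,
SVM, ROI logic, tiling, statistics — is correct on trichrome-like color and
texture statistics, not that the trained models would transfer to real
scans; the printed cross-validation figure on real slides is treated as a
synthetic analogue target, not a reproduction.

## Simulated rater

`generate_annotations()` plays the investigator: per class it places small
square polygons strictly interior to the class region — the class mask is
eroded by the feature window radius first, so every training pixel's window
is pure. Two refinements mirror how a careful rater works: annotations
rotate across every anatomical context a class appears in (collagen exists
in septa, masses and collars; background is both free glass and alveolar
lumina), and the high-magnification model — which only ever runs inside the
alveolar ROI — is annotated on alveolar structures alone, because training
it on peri-bronchial or mass collagen widened its decision region and
destabilized the readout under stain drift. Bronchus annotations are
restricted to wall and collar (not lumen air); purity there is with respect
to the label map, whose bronchus label covers the whole structure.

## Scale choices at desk size

The original pipeline classifies ~1 megapixel overviews of gigapixel scans;
the synthetic slides are a few megapixels, so the "low-magnification" level
(chosen as the pyramid level closest to 10^6 pixels) is only 2× below full
resolution. Two consequences were measured and drove design choices:

* Any pixel within one window radius of a class border has a mixed window
  and is locally ambiguous. With the initially considered 25 px low-mag
  window this band covered ~40% of fibrotic-mass area and pushed
  mass-border pixels into the bronchus class (mass recall 63%, readout bias
  about −10 points); with the default of **15 px** the band shrinks, the
  window still spans an entire bronchus ring (white lumen + red wall + blue
  collar — the signature that separates a bronchus from dense fibrosis), and
  mass recall rises to ~90%. Both structure sizes remain config keys.
* Mass and bronchus geometry are sized so structures are large relative to
  the window (masses) or comparable to it (bronchi), mirroring the real
  mm-vs-50 µm scale relation at desk size.

## Tiled map-reduce quantification

Full-resolution classification runs over 512×512 tiles. Each tile is read
with a halo of `floor(structure_size/2)` pixels so that window features at
tile borders equal the untiled computation; on 8-bit input all window sums
are exact integer arithmetic in doubles, so tiled and untiled runs agree
*exactly*, not just approximately (this is asserted in the tests). The map
step counts classes over the tile's ROI pixels (the low-magnification ROI is
upsampled nearest-neighbour); the reduce step is an associative element-wise
sum, so tile order — or a parallel worker pool — cannot change the result.

## Numerical choices

* **Variance** uses the $|W|-1$ divisor, consistent with the edge factor.
* **Edge factor per channel**: whether the original computes it per channel
  or on luminance is not documented; per channel is implemented and flagged
  as an assumption.
* **Mass readout denominator** excludes bronchi *and* background: the
  figure-level definition names only bronchi, but a denominator including
  background would depend on the scanned frame.
* **Collagen readout denominator** excludes background (alveolar air):
  saline-control collagen percentages in the low single digits are only
  consistent with a tissue-area denominator. A `denominator = "roi"` switch
  exists.
* **Total collagen** is never given a printed formula by its sources; the
  implemented definition is
  `100 * (collagen + mass_area) / (collagen + lung_tissue + mass_area)`
  with exclusion-map counts rescaled to level-0 pixels and bronchi excluded
  throughout; it is declared in the output metadata rather than asserted as
  canonical.
* **Mann-Whitney**: exact two-sided p (via the Wilcoxon rank-sum
  distribution) when `min(n, m) <= 8` and tie-free, else normal
  approximation with tie correction and continuity correction. Figure-level
  statistics use Mann-Whitney; an unpaired Welch t-test is available as a
  flag. No multiple-testing correction by default (a Holm option exists).
* **QC**: collapsed/empty slides are flagged (tissue fraction or alveolar
  fraction below thresholds), never deleted; flagged slides are dropped from
  group statistics. A manual override list reproduces a visual QC decision.
* **Degenerate inputs**: empty masks are empty results, not errors; an
  all-background exclusion map makes the readouts an explicit
  undefined-readout error rather than 0/0.

## Cross-validation analogue target

The printed model accuracy (95.47% mean over 10 folds) was measured on real
slides. The synthetic analogue builds six fixture slides spanning the full
stain-drift range, auto-annotates both models' classes, samples 40,000
pixels in total — 20,000 per detection model, since a single SVM over the
union of both label sets would conflate the two magnifications' background
classes — and reports the mean fold accuracy pooled over both models'
stratified 10-fold cross-validations. Because training pixels are pure
interior pixels of well-separated color classes, this analogue accuracy is
expected to sit above the printed figure; it validates the training/CV
machinery, not the difficulty of real histology.

## Known limitations

* The RFF + coordinate-descent SVM approximates an exact kernel SVM; with
  256 features the decision boundaries are smooth approximations. For the
  strongly separated trichrome classes this is immaterial; for subtler
  problems `n_rff` should be raised.
* Border pixels (within one window radius of a class boundary) are
  intrinsically ambiguous at desk scale. For the mass readout this costs a
  few percentage points (mean absolute error ~3–4 points over the recovery
  sweep). For alveolar collagen it is the dominant error: synthetic septa
  are 12 px wide against a 5 px window, so about half of all septal pixels
  sit within one window radius of an air boundary (septa are 12 px against
  a 5 px window). When training and test stains match, the absolute value is
  still recovered closely; under stain drift between fixtures and test
  slides the boundary pixels' assignments shift and the absolute collagen
  percentage is over-counted severalfold. The readout remains strictly
  informative — monotone in the true collagen burden (Spearman ≥ 0.9 in the
  acceptance sweep) and able to separate treatment groups — but its absolute
  scale is not comparable to values measured on real 40x scans, where septa
  span tens of pixels and the boundary share is small. Tests therefore
  assert recovery of the mass percentage, monotone tracking for collagen,
  and rank agreement (not absolute agreement) of per-tile collagen counts
  with ground truth.
* The TIFF layer implements uncompressed baseline TIFF only (verified
  against an independent reader); it is an interchange format for this
  package, not a general TIFF library.
* `pixel_size_um` is metadata only: no physical value is asserted for the
  source scanner, and no readout depends on it.
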