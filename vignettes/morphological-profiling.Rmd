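---
title: "Morphological profiling of endothelial monolayers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological profiling of endothelial monolayers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assay in one paragraph

Confluent endothelial monolayers respond to circulating inflammatory
mediators with characteristic morphological changes: F-actin stress fibers
appear, VE-cadherin adherens junctions become irregular, cells elongate,
and the mitochondrial network fragments into puncta. `vasoprofile`
implements the computational half of a high-content assay built on these
phenotypes: 4-channel plate images (nuclei, junctions, F-actin,
mitochondria) are quality-controlled, corrected for uneven illumination,
segmented into single cells, summarized as >= 800 morphological features
per cell, reduced by factor analysis to a handful of interpretable
factors, averaged into one fingerprint per well, condition, or sample, and
finally stratified by supervised multivariate models (LDA, PLS) under
repeated hold-out cross-validation. A seeded synthetic image generator
with exact ground truth stands in for the wet-lab experiments so that
every stage is testable end to end.

## The synthetic monolayer generator

`generate_site()` draws a confluent "cobblestone" monolayer as a perturbed
anisotropic Voronoi tessellation around Poisson-disk (dart-throwing)
nucleus centers. Geometry and noiseless rendering happen on a padded
canvas that is cropped to the requested frame, so frame-edge cells have
out-of-frame neighbours and edge statistics match the interior — as in a
real cropped field of view. Cells whose center falls outside the frame
remain visible in the masks (what a detector actually sees) but carry no
ground-truth row; `truth$n_visible_nuclei` counts everything visible.

The phenotype parameters and what they render:

* `cell_density` — cells per site; the dart-throwing minimum distance is
  scaled so the target is met within a few percent.
* `elongation` (mean aspect ratio, >= 1) — anisotropic Voronoi metric per
  cell, with a matching elongation of the nucleus ellipse.
* `stress_fiber_level` — the fraction of cells rendered with 3–5 bright
  linear F-actin fibers along the cell axis. The noiseless actin layer's
  oriented linear-structure energy increases strictly with this parameter
  (property-tested with a brute-force oriented line filter).
* `junction_irregularity` (px) — the amplitude of a smooth random warp
  applied to the coordinates before the Voronoi assignment, which makes
  borders wiggly; connectivity of every cell region is repaired and
  guaranteed.
* `mito_fragmentation` — interpolates between elongated filament networks
  (persistent random walks, 4-connected traces) and small puncta. Puncta
  count and brightness are balanced so that total mitochondrial signal is
  approximately conserved across fragmentation levels — fission
  redistributes mass rather than removing it — which keeps the per-plate
  intensity QC from confounding phenotype with image quality. The mean
  connected-component size of the noiseless layer differs by far more than
  the 5x used in tests.
* `channel_snr` — Poisson shot noise with gain `2*snr^2` plus Gaussian read
  noise of sd `0.25/snr`, on a [0,1] scale that maps to 16-bit on disk;
  `vignette_amplitude` — multiplicative radial shading, 1 at the center,
  `1 - amplitude` in the corners; `artifact_rate` / `artifact_kinds` — a
  per-site probability of an out-of-focus blur, a blank channel, a
  saturated patch, or a bright debris blob.

What the generator does **not** emulate: photorealistic textures, 3-D
stacks / max projections (sites are single-plane), cell division and
motion, optical point-spread differences between channels, and any actual
plasma dose–response biochemistry — groups differ only through the
monotone phenotype parameters above. Passing tests therefore demonstrate
that the *pipeline* recovers what the generator encodes, not that the
features are biologically sufficient on real images.

`plate_design()` + `generate_plate_set()` arrange samples in groups across
plates (round-robin, so plates carry a balanced group mix), with 3
replicate wells per sample and 8 sites per well by default, and a
multiplicative per-plate intensity effect for batch-effect studies.

## Image QC and illumination correction

`compute_qc()` reports, per image: intensity sum, median, sd, the
0.01/0.25/0.75/0.99 quantiles (type-7 linear interpolation — stated so
oracles match), a saturated-pixel fraction, and a focus score defined as
the slope of the radially averaged log power spectrum vs log frequency
over 0.05–0.45 cycles/px. Blur suppresses high frequencies and steepens
the decay, so higher = sharper; the score is NA for constant images.

`flag_outliers()` is an automatic surrogate for the histogram inspection
used in practice: per plate and channel, an image fails when its focus
score drops more than `k_mad` (default 5) robust deviations below the
median, when its intensity sum leaves the median ± 5 MAD band, when more
than 5% of pixels are saturated, or when it is blank. The site-discard
rule is then absolute: if any channel of a site fails, all images of that
site fail (reason `sibling_channel_failed`), so passing images per site
are always 0 or the full channel count.

`estimate_illumination()` implements an iterative robust retrospective
estimate: start from the smoothed per-pixel median across images,
flat-field the stack with the current field, mask pixels deviating more
than 30% from the per-pixel median of the flat-fielded stack (foreground
rejection), re-estimate from unmasked pixels, smooth, renormalize to
spatial mean 1, and repeat (5 iterations or until the field changes by
less than `tol`). The smoothness constraint is a **low-order polynomial
surface** (total degree 2 by default). We initially used a large Gaussian
blur as the smoother, but Gaussian smoothing of a sloped field is
systematically biased near the image border — one-sided windows flatten
the vignette — which capped the achievable correction of a strong corner
shading at well under the package's own acceptance bar no matter how many
images were used; a degree-2 surface represents radial vignettes
essentially exactly and recovers synthetic fields at r > 0.95 from a dozen
images. The Gaussian variant remains available (`smoothing = "gaussian"`).
Because the field is normalized to mean 1, plate-wide mean intensity is
conserved to within 1%.

## Segmentation

Nuclei: mild Gaussian smoothing (sigma 1.5), local-mean threshold (51-px
window, offset 2% of the dynamic range above the local mean), Euclidean
distance transform, watershed on the distance map to split touching
nuclei, and a minimum-area filter (30 px) for debris.

Cells: nuclei-seeded, image-weighted Voronoi propagation, implemented as a
Dijkstra relaxation in C++ with explicit source tracking: a pixel's cost
is the accumulated absolute junction-intensity difference along the
claiming path plus `lambda` times the *true Euclidean distance* to the
seed pixel the claim originated from. Tracking the source pixel (rather
than accumulating chamfer steps) matters: with a uniform junction image
the partition then reduces to the geometric Voronoi diagram of the seeds
to within a pixel, a property the test suite checks against a brute-force
nearest-seed oracle, whereas an 8-neighbour chamfer metric deviates by
several pixels at realistic seed distances. Bright VE-cadherin ridges cost
intensity to cross in both directions, so boundaries lock onto junction
lines. `lambda` (default 0.02) trades geometric regularity against
junction guidance; the default, along with the threshold window and
minimum nucleus size, was calibrated on the synthetic fixtures (mean
per-cell IoU >= 0.7 against ground truth), not on any external dataset.
`filter_cells()` removes labels by nucleus/cell size or frame contact from
both masks jointly and relabels consecutively; border cells are kept by
default.

Conventions stated once and used everywhere: rasters are indexed
[row, col] with origin top-left (x = column, y = row), labels are positive
consecutive integers, 0 is background, intensities live on [0, 1] and are
written to disk as 16-bit TIFF.

## The single-cell feature manifest

`feature_manifest()` enumerates every output column; the extractor asserts
against it, so the two cannot drift. 835 features from six families:

* **shape** (cell, nucleus): area, 4-edge perimeter, boundary radii
  (mean/sd/min/max), equivalent diameter, form factor, nucleus/cell area
  ratio. A one-pixel region has perimeter 4 and eccentricity 0 by
  construction.
* **moment** (cell, nucleus): normalized central moments up to order 2 and
  the derived ellipse: eccentricity, major/minor axis, orientation.
* **intensity** (4 channels x 5 compartments x 21 statistics): the
  compartments are cell, nucleus, cytoplasm (cell minus nucleus), a 2-px
  membrane band, and a 3-px peri-nuclear ring; statistics include
  integrated intensity, location/scale/order statistics, histogram
  entropy, skewness, kurtosis, and mass displacement (geometric vs
  intensity-weighted centroid). Integrated intensity is exactly additive:
  cell = nucleus + cytoplasm.
* **texture** (4 channels x 3 compartments x 13 x 2 distances): classical
  gray-level co-occurrence statistics, symmetric GLCM quantized to 64
  levels between the region's own min and max, accumulated at distances 1
  and 3 px, averaged over the four principal directions (which makes the
  features invariant to 90-degree rotation); regions under 25 px yield NA.
* **distribution** (4 channels x 6): intensity fractions in 4 concentric
  rings of the normalized radius rho = r / (r + d_border) between nucleus
  centroid (rho = 0) and cell border (rho = 1), plus the intensity-weighted
  mean and CV of rho. Fractions sum to 1; zero-intensity cells fall back to
  ring-area fractions and are flagged.
* **colocalization** (junction/actin/mito pairs x 3 compartments, plus
  nuclei-vs-each within the nucleus): Pearson correlation (NA on constant
  signal), double-thresholded Manders M1/M2 with per-cell Otsu thresholds
  (identical channels give exactly 1, disjoint above-threshold supports
  give 0), and the overlap coefficient.

The feature families follow the naming
`<channel>.<compartment>.<family>.<stat>`; all values depend on region
content only, never on absolute position (translation invariance is
property-tested). Missing values are imputed by per-plate column medians
(`impute_missing()`), with the imputation mask kept as an attribute and an
`imputed_any` flag per cell — imputation happens *before* z-scoring, and
flagged cells can be excluded in sensitivity analyses.

The original assay description fixes the families and the roughly
800-dimensional profile but not the exact feature list; this manifest is
one documented, oracle-testable realization of it.

## Fingerprints

`normalize_per_plate()` z-scores every feature within each plate
(population sd, ddof = 0 — stated so oracles match) before plates are
combined, removing additive and multiplicative plate effects exactly (a
constructed batch-shift fixture normalizes to identical tables).
Zero-variance columns within a plate are set to 0 and reported.

`fit_factor_model()` reduces the normalized matrix by principal-axis
factor extraction: loadings are leading eigenvectors of the feature
covariance scaled by the square roots of their eigenvalues. "Variance
captured" has no canonical definition for factor analysis, so the package
fixes one formula and tests it: explained variance = sum of squared
loadings / total variance of the normalized data. The factor count k is
the smallest k reaching the `variance_target` (default 0.80, the assay's
design constant), falling back to `k_max` with a warning. No rotation is
applied by default (the variance accounting stays simple and the fit is
deterministic); varimax is available and leaves the captured variance
unchanged. Scores are the least-squares regression of the centered data
onto the loadings; a duplicated cell scores identically, and score column
means vanish over the fitting data. On a 5-factor linear latent model with
2% noise the selection rule recovers k = 5 and the loading subspace to
principal angles under 10 degrees across seeds.

`aggregate_fingerprints()` averages cells per well, per condition, or per
sample. Sample-level aggregation pools cells across the sample's replicate
wells (cell-weighted), not mean-of-well-means — one vector per sample built
from all of its single-cell data; the well level gives the alternative when
a sensitivity analysis wants equal well weights. `scale_fingerprints()`
standardizes each factor across entities (idempotent, affine-invariant)
and is refit inside every cross-validation training fold, never on pooled
data. `factor_composition()` attributes each factor to (channel, family)
groups by summed squared loadings, normalized by the grand total — the
heat-map that makes factors interpretable.

## Supervised stratification

`fit_lda()` is Fisher LDA with optional shrinkage of the pooled
within-class covariance toward a scaled identity — applied automatically
with the smallest shrinkage that makes the scatter well-conditioned, and
reported. With around 10 factors and tens of entities the scatter is
occasionally singular (collinear factors), which plain solvers reject.
The package's own implementation is cross-checked against `MASS::lda` on
well-conditioned data and against the closed-form Fisher direction for two
classes. Coefficient vectors per factor are exported for biplot overlays
(`biplot_data()` scales them uniformly into the score range; angles are
preserved exactly).

`cross_validate_classifier()` repeats: hold out 10–20% of *entities*
(wells or samples, never single cells — holding out cells of a well whose
siblings were trained on would leak), fit the scaler and the LDA on the
remaining entities only, predict the held-out ones. Splits are stratified
by class by default so small classes survive in every training fold.
Confusion counts aggregate over repeats and are row-normalized per true
class, so the diagonal reads as the fraction of each class predicted
correctly. `cross_validate_regressor()` follows the same protocol with a
PLS regression (fit via mixOmics), choosing the component count (up to 5)
by an inner 5-fold cross-validation on the training entities, and reports
out-of-fold R-squared = 1 - SSres/SStot per repeat with mean and sd.
Permutation-chance behaviour (classifier at 1/C, regressor at R-squared
<= 0.05) and a leakage guard (corrupting test-fold labels cannot change
fitted parameters) are property-tested.

## Reference datasets and problem sizes

Two canned designs define the package's reference conditions:

* `standard_assay_design()` / `standard_assay_params()`: 2 plates with a
  1.15x batch effect, 3 phenotype groups (quiescent, activated, severe) x
  2 samples x 3 replicate wells x 8 sites of 160 px at 35 cells/site —
  144 sites, about 5,000 cells, mild vignetting (0.25) and a 2% artifact
  rate so QC and illumination correction run under load. The severe group
  is dominated by mitochondrial fragmentation (0.80 vs 0.15), with
  junction, actin and elongation shifts grading from quiescent through
  activated. No phenotype magnitudes are prescribed by the assay
  description; these effect sizes are the package's documented choice and
  are deliberately strong enough that group structure, not generator
  noise, drives the factor space.
* `stimulant_design()` / `stimulant_params()`: one plate, an unstimulated
  condition and two strongly perturbed conditions (a cytokine-like
  elongation + stress-fiber phenotype and an endotoxin-like junction +
  mitochondria phenotype), 5 replicate wells x 8 sites each, classified at
  the well level by repeated 20% hold-out.

These sizes keep a full pipeline run to a couple of minutes on one CPU
while staying at the scale the assay design describes (3 wells x 8 sites
per sample; ~5,000 cells feeding the factor model).

## Numerical choices and degenerate inputs

* Quantiles use R's type-7 linear interpolation everywhere.
* z-scores and fingerprint scaling use the population sd (ddof 0).
* Loading signs follow a fixed convention (largest-magnitude element
  positive), making the factor model fully deterministic; `seed` is stored
  for provenance only.
* Blank images: 0 nuclei, empty (not failing) segmentation results, empty
  feature tables with intact headers.
* One-pixel regions: perimeter 4, eccentricity 0; sub-25-px texture
  regions: NA then imputed; zero-variance Pearson: NA; zero-intensity
  radial distributions: ring-area fractions, flagged.
* Ties in the propagation queue resolve by cost with a 1e-12 slack;
  `lambda = 0` is lifted to 1e-9 so a uniform image still yields the
  geometric Voronoi partition rather than arbitrary ties.

## Known limitations

* The generator's phenotypes are low-dimensional by construction; real
  plasma-induced morphologies are richer, and factor counts fitted here
  (k around 25–30 for 80% variance) need not transfer to real data.
* Illumination estimation assumes the field is shared within a plate and
  channel and smooth at polynomial order 2; strong local optical defects
  would need the Gaussian smoother or more images.
* The propagation metric uses accumulated intensity differences; very
  noisy junction channels benefit from the default mild smoothing upstream
  but are not denoised inside the segmenter.
* Cross-validation treats entities as exchangeable; with patient samples
  spread across plates the plate effect is removed beforehand by
  normalization rather than modeled in the CV splits.
* Per-plate z-scoring removes *everything* a plate has in common. If a
  group is completely confounded with a plate (e.g. one sample per group
  on separate plates), the group signal is removed together with the batch
  effect and classification collapses. Designs must distribute every group
  across every plate — `plate_layout()` does this round-robin, and the
  reference design has 2 samples per group over 2 plates for exactly this
  reason. The same balancing requirement applies to real plate layouts.
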