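---
title: "Quantifying spheroid outgrowth: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spheroid outgrowth: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Multicellular spheroids embedded in a collagen matrix shed migrating cells:
endothelial cells form sprouts, fibroblast-like synoviocytes extend
dendritic processes, and macrophages detach and wander off individually.
In a multi-channel confocal image of such a spheroid, two regions carry the
biology of interest:

* the **core** — the cohesive central cell mass remaining after migration;
* the **outgrowth** — everything cell-covered outside the core, comprising
  cells still associated with it (sprouts, extensions) and non-associated
  detached cells.

From a segmented image, `outgrowthr` reports the **outgrowth/core area
ratio** (the headline measure of migratory activity), per-channel
**integrated densities** — the sum of a channel's pixel intensities over a
region, identically mean intensity × area — and their **percentage of the
total integrated density**, which under the assumption that fluorescence is
proportional to cell amount estimates how much of a labeled cell type sits
in each region, plus the **number of individual cells outside the core**,
obtained by blob detection on the channel of the detached cell type.

## Pipeline

1. **Projection** (`project()`): confocal Z-stacks are collapsed to one 2D
   image per channel. The default operator is the per-pixel maximum: for
   sparse fluorescent structures it preserves thin sprouts that appear in a
   single optical section, where a mean would dilute them. Sum and mean
   projections are available; the operator is a parameter because nothing
   about the downstream measurements depends on which one is chosen, only
   on it being applied per channel without mixing channels.
2. **Pixel classification** (`train_pixel_classifier()`,
   `apply_pixel_classifier()`): a random forest (100 trees, balanced class
   weights, fixed seed, single-threaded inference so results are
   bit-reproducible) maps per-pixel feature vectors to
   background/core/outgrowth. Features are multiscale — Gaussian
   smoothings, gradient magnitude, Laplacian, difference of Gaussians,
   optionally structure-tensor eigenvalues, at scales of 1–8 px — computed
   on every channel, because the core carries all cell types while
   outgrowth structures are channel-specific. Borders are handled by
   reflection. A deterministic fallback (`threshold_fallback()`, fixed or
   Otsu threshold on the summed composite) provides a classifier-free
   pathway.
3. **Region refinement** (`refine_regions()`,
   `derive_regions_from_cellmask()`): raw labels are consolidated into
   exactly one 4-connected core (largest candidate after opening and hole
   filling; ties go to the component nearest the image centre), stray
   core islands are relabeled outgrowth, and outgrowth speckle below
   `min_object_area` is dropped. The two-class pathway instead erodes thin
   structures away (radius `r_core`) to find the core and takes the mask
   remainder as outgrowth.
4. **Quantification** (`measure_regions()`,
   `detect_cells_outside_core()`): areas, ratio, integrated densities,
   regional percentages; scale-normalised Laplacian-of-Gaussian blob
   detection for cell counts.
5. **Cohort aggregation** (`run_pipeline()`, `condition_summary()`,
   `paired_summary()`): per-condition n/mean/SD/SEM and fold changes
   against a reference condition, plus per-batch paired tables for
   repeated-measures designs.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `sigmas` (features) | 1, 2, 4, 8 | px | spans sprout width (~3 px) to core-scale context |
| `num_trees` | 100 | — | forest accuracy saturates well before this on pixel features |
| `r_open` (refine) | 3 | px | removes core fragments thinner than a sprout without attacking the core |
| `min_object_area` | 9 | px² | drops speckle while keeping single detached cells (radius ≥ 2 px) |
| `r_core` (two-class path) | 5 | px | above half the sprout width, far below the core radius |
| `sigma_range` (detection) | 1.5–4 | px | matches cell radii 2–6 px (blob of radius r peaks at σ ≈ r/√2) |
| detection `threshold` | 0.2 × channel max | response units | keeps blobs at half nominal brightness, rejects noise maxima at ≤ 20% noise |
| `min_separation` | 5 | px | below twice a cell diameter; closer maxima are one cell |
| `exclusion_margin` | 2 | px | suppresses rim artefacts of the core boundary |

Percentages of total integrated density use core + outgrowth as the total:
those are the two measured areas, and background signal is noise rather
than cells. `include_background = TRUE` adds the background term for QC.
The ratio is reported as missing when the core is empty — never as a
division by zero — and such images are excluded from ratio and percentage
condition summaries (and logged), while their remaining metrics are kept.

## The synthetic generator and what it does (not) show

Real validation data with pixel-exact truth does not exist, so the package
ships a generator (`spheroid_scene()`, `render_scene()`) that emulates the
assay's morphology: a bright core disk carrying all channels, anti-aliased
sprouts radiating from the rim carrying the fibroblast and endothelial
channels with per-sprout intensity jitter (0.8–1.2), and detached cells as
small disks in the macrophage channel placed by rejection sampling with a
minimum pairwise distance of twice their radius, so the planted count is
unambiguous. Gaussian read noise and optional Poisson photon noise are
applied only after the ground truth is frozen from the noiseless
rendering; truth is therefore exact by construction. Intensities are
quantised to non-negative integers, as a camera would record them.

Sprout angles are stratified (evenly spaced sectors with uniform jitter):
radially migrating cells spread around the rim, and stratification keeps
the union area of the sprouts close to the sum of per-sprout areas, so the
analytic expectation used by `make_condition_set()` — sprout count × length
× width plus detached disk areas — stays faithful when a fold change is
imposed by rescaling sprout count and length.

Default study conditions: 256 × 256 px scenes, core radius 40 px, 10
sprouts of length 60 ± 10 px and width 3 px, 25 detached cells of radius
3 px in an annulus 55–120 px from the centre, nominal channel intensities
200/180/160, noise standard deviations up to 40 (20% of nominal).
Replicated conditions use 8 replicates per arm, mirroring the 2–7
biological replicates typical of the assay.

What passing tests on this generator do **not** show: robustness to uneven
illumination, bleaching, out-of-focus haze, touching spheroids in one
field, strongly branched or curved sprouts (the generator draws unbranched
straight sprouts; branching is off by default), or channel crosstalk. On
real data the intended workflow is the one the package mirrors: train the
classifier on a pool of representative annotated pictures, inspect each
segmentation, and override the model per image in the manifest
(`model_override`) where it fails.

## Numerical choices and degenerate inputs

* All morphology uses 4-connectivity — conservative separation of
  barely-touching sprout tips from the core.
* Area ties between core candidates are broken by centroid proximity to
  the image centre (fields image one spheroid, roughly centred).
* The final core in `refine_regions()` is the original-label component
  containing the winning opened candidate, hole-filled; refining an
  already-clean map is therefore the identity, and refinement is
  idempotent.
* A core touching the image border is kept but flagged: its area is a
  lower bound.
* Probability maps sum to 1 per pixel (tolerance 1e-6); argmax ties break
  toward background < core < outgrowth.
* Classifier training records per-class label counts, balanced weights and
  a stratified 20% hold-out accuracy before refitting on all labels.
* TIFF round-trips are bit-exact for integer intensities up to 16 bits;
  axis layout and pixel size travel in embedded OME-XML metadata.
* An empty condition after per-image failures aborts the batch; a single
  failed image never does.

## A worked validation

```{r, eval = FALSE}
library(outgrowthr)

# train on two representative scenes (one near-noiseless, one at 20% noise)
pool <- lapply(c(10, 40), function(ns)
  render_scene(spheroid_scene(seed = 77 + ns, noise_sigma = ns)))
model <- train_pixel_classifier(
  images      = lapply(pool, \(r) project(r$stack)),
  annotations = lapply(pool, \(r) annotate_from_truth(r$truth, 0.02, seed = 1)),
  seed = 1
)
glance(model)

# quantify an unseen noisy scene and compare with its ground truth
r   <- render_scene(spheroid_scene(seed = 555, noise_sigma = 40))
img <- project(r$stack)
lm  <- refine_regions(apply_pixel_classifier(model, img)$labels)
glance(measure_regions(img, lm))$outgrowth_core_ratio
r$truth$true_outgrowth_area / r$truth$true_core_area
```

The full validation — mask partition and integrated-density conservation,
the definitional identity of integrated density, the 20-scene segmentation
sweep, ratio recovery and fold monotonicity, planted-count recovery, the
two-condition 2× cohort and byte-identical reruns — lives in the test
suite (`tests/testthat/test-acceptance.R`) and in `scripts/acceptance.R`,
which recomputes the same quantities from scratch. Problem sizes there
(20-scene sweep, 8 + 8 replicate cohort, counts up to 200 cells) are the
package's validation conditions stated above.

## Known limitations

* Sprout-level morphology (count, length, branching, connected versus
  detached classification) is out of scope; the method reports areas,
  intensities and counts only, and distance-based features are a future
  extension.
* Inferential statistics are deliberately absent: the output tables are
  tidy inputs for any statistics environment.
* The classifier gives no automatic adequacy score for a segmentation;
  checking output and switching models per image is a manual,
  semi-automated step, as in the assay protocol the package follows.
* 3D (non-projected) measurements are not supported; projection discards
  axial information by design.
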