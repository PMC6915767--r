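---
title: "Quantifying synapses and synaptic pathology from array-tomography stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synapses and synaptic pathology from array-tomography stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arraytomo)
```

## The measurement problem

Array tomography resolves individual synapses by physical rather than
optical sectioning: resin-embedded tissue is cut into ribbons of
ultrathin (70 nm) serial sections, each section is immunostained and
imaged, and the images are computationally re-stacked into a 3D
volume. Presynaptic terminals (synaptophysin) and postsynaptic
densities (PSD95) appear as discrete fluorescent puncta a few hundred
nanometres across. In Alzheimer's-model tissue two further channels
matter: pathological proteins (tau, oligomeric amyloid-beta) that may
accumulate *inside* synapses, and plaque stains (Thioflavin S for
fibrillar cores, a pan-amyloid antibody that additionally reveals the
oligomeric halo around each core).

The quantities of interest are per-animal: synaptic punctum density
(per µm³), split by distance to the nearest plaque edge (nearer or
farther than 20 µm), and the fraction of synaptic puncta "positive"
for each pathological marker, where positivity means at least half of
the punctum's voxel volume overlaps the marker's thresholded mask.
The animal (or human case) is always the experimental unit; statistics
are computed over per-animal summaries, never over pooled synapses.

`arraytomo` implements this pipeline end to end —

1. **simulate** (or read) calibrated multi-channel serial-section stacks,
2. **register** sections by translation-only rigid alignment,
3. **segment** each channel per section with a union of automatic
   thresholds,
4. **reconstruct** 3D puncta and discard single-section noise,
5. **plaque** detection, edge-distance fields, burden and halo metrics,
6. **colocalize** synaptic puncta with marker masks under the
   50%-volume rule,
7. **summarize** per animal and test groups nonparametrically —

plus open-field trajectory metrics for the behavioral arm of such
studies.

## The synthetic-data generator

No public microscope data accompanies this analysis at workable scale,
so the package carries a first-class generator (`synth_params()`,
`generate_stack()`) whose ground truth drives every test. It renders:

* **Geometry.** Sections of 0.07 µm; default xy sampling 0.1 µm/px
  (typical of a 63x/1.4 NA acquisition; configurable — physical
  anisotropy always lives in the calibration metadata, never in
  resampling). Arrays are indexed `[row, col, section]`, the natural
  order for R image containers.
* **Puncta** as order-8 super-Gaussian (near top-hat) footprints whose
  half-maximum radius is drawn around 0.2 µm, spanning on average 5
  consecutive sections with uniform intensity across the span: at
  70 nm sectioning, a ~0.4 µm object is effectively uniform over its
  few sections, and compact steep-edged footprints are what
  diffraction-limited puncta look like at this pixel size. Densities
  default to 0.7 (presynaptic) and 0.9 (postsynaptic) per µm³ — the
  order of cortical synapse density, with the post/pre ratio seen in
  large array-tomography counts. A hard-core minimum separation
  (default 0.7 µm centre-to-centre for same-channel puncta with
  overlapping section ranges) keeps objects resolvable, as real
  *quantified* puncta are by construction.
* **Markers.** Each punctum is independently tau- and/or
  amyloid-beta-positive with configurable probabilities (defaults 1%
  and 5%, inside the range such studies report). Positive puncta get a
  co-centred marker blob 1.5x their radius, so true positives satisfy
  the 50% rule under any reasonable segmentation.
* **Plaques** as a bright core disc present in both the ThioS and
  pan-amyloid channels and a dimmer (45% amplitude) halo disc in the
  pan-amyloid channel only, spanning all sections (a plaque is an
  order of magnitude larger than a 1 µm ribbon depth).
* **Noise.** Constant background (100 counts) plus Gaussian noise
  (sd 25) against a punctum amplitude of 500 (jittered 0.8–1.2x),
  quantized to 16-bit integers; single-section "specks" at 0.05/µm³
  emulate staining debris.
* **Misalignment.** Independent per-section rigid translations
  (sd 2 px), whole-pixel by default (lossless to undo), optionally
  subpixel via bilinear resampling. Section 1 is the reference.

The truth object records every rendered punctum and speck, the applied
shifts, per-channel half-maximum masks, and the pre-misalignment
stack, so recovery can be scored at voxel, object and rate level.

What the generator does **not** emulate: optical PSF anisotropy and
chromatic shifts, tissue deformation and section folds, staining
gradients within a section, autofluorescence structure, and clustered
(non-hard-core) punctum spatial statistics. Passing tests therefore
demonstrate that the algorithms recover what they claim from data with
realistic geometry, intensity and noise — not that any specific
biological effect size would be detected in real tissue.

```{r generator}
p <- synth_params(field_size_px = c(96, 96), n_sections = 10, seed = 1)
g <- generate_stack(p)
g$stack
nrow(g$truth$puncta)
```

## Registration

Alignment uses a translation-only rigid model: at 70 nm the dominant
acquisition artifact is a per-section stage offset; rotation is left
as an extension hook. Pairwise displacements between sections at lags
1–3 are estimated by phase correlation — whitened cross-power for a
robust integer peak, then subpixel refinement by locally upsampled
(factor 50) raw cross-correlation, which is less noise-sensitive than
refining the whitened surface. The redundant longer-lag measurements
are combined by least squares over the shift chain, cancelling the
drift that plain predecessor-chaining accumulates.

Numerical choices worth knowing:

* `upsample = 1` puts the estimator in **integer mode**: recovered
  shifts are whole pixels and applying them is a lossless index roll.
  This is the pipeline default because whole-pixel misalignments are
  the common case and integer corrections never blur; set
  `registration: {upsample: 50}` in the config for subpixel data.
* Subpixel application offers bilinear interpolation (local, no
  ringing; default) or an exact Fourier phase ramp (perfectly
  self-inverse, but rings at hard edges); out-of-field pixels are
  zero-filled and returned in a valid-region mask.
* A blank section cannot be measured against; it inherits its
  predecessor's shift with a warning, and later sections bridge past
  it through the lag-2/3 measurements.
* The channel driving alignment defaults to the nuclear stain when
  present, else the presynaptic channel — dense, stain-independent
  structure; configurable because acquisitions differ.

## Segmentation

Each channel is binarized per section — thresholds must adapt to
section-to-section staining variation — as the **union** of automatic
threshold algorithms: a global bimodal method (Otsu) catches bright
puncta, a tail-sensitive method (triangle) catches dim ones. The
union contract is monotone: adding a method never removes foreground.
Three guards keep automatic thresholding honest:

* constant sections yield an empty mask (never a full one);
* a method whose foreground would exceed `max_foreground` (default
  25%; 60% for plaque channels) has degenerately split the background
  of a signal-free image and is dropped;
* for channels that may carry no signal at all (plaque channels in
  control animals), `min_contrast_mads` additionally requires the
  median foreground intensity to exceed the median background by 4
  background-MADs, else the section is declared empty.

In-plane connected components smaller than `min_object_px` (default 2;
single pixels are indistinguishable from shot noise) are removed — a
deliberate, documented knob, since the defining noise filter of this
analysis operates in 3D (below). Plaque channels use Otsu alone for
the fibrillar core (tail-sensitive methods over-extend bright edges)
and the lower threshold of three-class Otsu for the pan-amyloid
channel, whose histogram is trimodal (background, halo, core) and
defeats single-threshold Otsu.

## 3D reconstruction and the single-section rule

Foreground voxels are linked with 8-connectivity within a section and
across consecutive sections wherever 2D footprints share at least one
xy pixel — the weakest linkage consistent with treating single-section
objects as noise. Linking is strictly consecutive by default; a
`gap_tolerance` option can bridge a missed detection, but defaults to
0 because tolerating gaps trades noise suppression for sensitivity in
an unquantified way. Objects spanning only one section are then
removed (`filter_single_section()`, idempotent); this is the pipeline's
principal noise filter, and it is why specks and most threshold noise
never reach the density or colocalization stages. Volumes are voxel
counts times the voxel volume; centroids are unweighted voxel means,
because masks — not intensities — are the unit of analysis throughout.

## Plaques, distances, burden

Plaque detection reuses the segmentation machinery (automatic,
reproducible — a manual blinded threshold cannot live in a pipeline),
followed by a per-section minimum area (default 20 µm², guarding
against puncta-scale debris). The edge-distance field is computed
exactly for anisotropic voxels: per-section 2D Euclidean distance maps
are combined across sections with the physical z offset,
`d = min_s sqrt(d2D_s^2 + (dz)^2)`; distance is 0 inside a plaque and
infinite in a plaque-free field. Proximity is classified strictly:
**near** means `< 20` µm from the fibrillar core edge, so exactly
20 µm — and infinitely far — is **far**. Distances are measured from
the ThioS-defined core edge (the conventional definition of "plaque
edge"), with the pan-amyloid edge available as an option; ROI
proximity uses the ROI centre (configurable), and analysis ROI size is
a parameter (default 10 µm square) because conventions vary.

Burden metrics (percent area, object count, mean object area — absent,
not zero, when no objects) treat sections as independent 2D images,
matching how histological burden is scored. The oligomeric halo is
pure set arithmetic, pan-mask AND NOT core-mask. Regional volumes
follow the section-sum rule: area x spacing, summed, doubled when one
hemisphere stands in for the brain.

## Colocalization

`overlap_fraction()` is exact voxel arithmetic; `classify_positive()`
reads "a minimum of 50%" inclusively, so exactly half qualifies. Each
marker is scored independently and "double positive" is the
conjunction of the independent calls — the conservative reading of
scoring markers "individually and in combination". Marker masks are,
by default, rebuilt from 3D-filtered marker objects
(`mask_from_puncta()`), so single-section marker specks cannot make a
synapse "positive"; the raw per-section mask remains available. Empty
strata report `n = 0` with an absent fraction — a stratum with no
synapses is missing data, not 0% positivity.

## Statistics

Group comparisons use the Mann-Whitney U test on per-animal values: U
from rank sums with midranks, the exact permutation distribution when
the combined sample is at most 12 with no ties (typical group sizes
here are 4–11), and the tie- and continuity-corrected normal
approximation otherwise; identical samples short-circuit to p = 1.
Tests are two-sided by default and uncorrected for multiplicity (a
Benjamini-Hochberg helper exists, off by default), matching standard
practice for these designs. The Mendelian-ratio check is the plain
chi-square goodness of fit against expected class proportions with
`k - 1` degrees of freedom. Parametric branches (ANOVA families) are
deliberately out of scope; the package exposes only the nonparametric
path plus descriptive summaries.

```{r stats}
mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p      # exact: 2/20 labelings
round(chi_square_upper_tail(6.41, 3), 3)      # the worked Mendelian value
```

## The pipeline and reproducibility

`run_pipeline()` executes all stages from one configuration (YAML or
list) and writes one CSV per stage table plus a JSON manifest carrying
a hash of the configuration, the seed and the package version. Every
stage is a pure function of (inputs, config, seed): reruns are
byte-identical at the CSV level, and all randomness flows from a
single seed per generated animal. A missing calibration fails
validation before any compute — pixel sizes are never assumed.

Test and validation problem sizes are chosen so the whole suite runs
in minutes on one core: fields of 9.6–25.6 µm, 6–15 sections,
5–12 seeds per recovery experiment, 2000 simulations for test
calibration. These sizes give binomial/Poisson error bars comfortably
inside the tolerances being asserted; nothing about the algorithms is
size-dependent beyond that.

## Known limitations

* Translation-only registration: ribbons with appreciable rotation or
  tissue deformation need an affine/elastic front end.
* Threshold methods are histogram-based; structured backgrounds
  (autofluorescence gradients) would need background subtraction
  first.
* Cross-section linking requires a shared xy pixel; at extreme
  misalignment residuals (> punctum radius) puncta fragment.
* Pre/post synapse *pairing* is out of scope — channels are quantified
  independently, as in the analyses this package reproduces.
* The generator's hard-core point process understates the clustering
  of real synapses; density recovery on clustered data would see more
  merging at equal nominal density.
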