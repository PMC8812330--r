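---
title: "Quantifying lipid droplet-mitochondria contact sites: methods and design"
author: "contactr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lipid droplet-mitochondria contact sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactr)
```

## The measurement problem

Lipid droplets (LDs) and mitochondria exchange lipids at membrane
contact sites, regions where the two organelles' membranes are apposed
within tens of nanometres. Electron microscopy resolves these contacts
directly but does not scale to hundreds of cells. In confocal
fluorescence microscopy the contact is below the resolution limit, but
the *co-occurrence* of the two organelle signals along the droplet
boundary is a workable proxy: where a mitochondrion wraps a droplet,
both channels are bright and of comparable intensity in the same
pixels. contactr turns that proxy into a per-cell measurement: each
contact becomes a one-pixel-wide line with a calibrated length, counted
and summed per cell together with full organelle morphometry.

The pipeline operates on single-section, three-channel images (nucleus
/ LD / mitochondria; 8-, 12- or 16-bit), calibrated in micrometres per
pixel (default 0.093 um, the acquisition this workflow targets).

## Pipeline stages and their assumptions

### Cell individualization without a membrane marker

The target preparations carry no cell-boundary stain, so cells are
delineated from what is available: the cytoplasmic organelle signals
plus the nucleus.

1. Each cytoplasmic channel is converted to 8-bit and multiplied by a
   *compensation* factor (default 0.2 per channel) so neither dominates
   the 255-valued binary nucleus mask they are added to. The result is
   a landscape whose dominant maxima are the nuclei.
2. Prominence-based maxima detection (prominence 100 of 255) finds one
   seed per nucleus; watershed-style flooding partitions the image into
   one region per seed, with one-pixel ridge ("limit") lines between
   regions.
3. Independently, the three channels are flattened ((R+G+B)/3 of the
   8-bit planes), median-filtered (disk radius 2) and Huang-thresholded
   into a whole-cell foreground mask. This step assumes the cell body
   is distinguishable from the background in the *combined* signal —
   in practice supplied by the mitochondrial network, cytoplasmic haze
   and the nucleus.
4. The foreground is cut along the limit lines (a per-pixel minimum),
   and 4-connected particle analysis keeps components of at least
   `min_cell_area_um2` (default 50 um^2) that contain at least one
   nucleus pixel. Anucleate fragments are segmentation debris by this
   definition and are dropped; border-touching cells are kept but
   flagged so users can filter them downstream.

The assumption to keep in mind: a cell whose organelles do not fill its
outline will be under-segmented (area too small), and two cells whose
cytoplasms interdigitate are split along an intensity ridge, not a
geometric one.

### Lipid droplet segmentation

Thresholding the LD channel is unreliable in real data (out-of-focus
halos, cytosolic dye background), which is why a trainable pixel
classifier is the primary route. Per pixel, a feature vector is built
from five families over a sigma ladder (default 1, 2, 4, 8, 16 px):
Gaussian blur, difference of Gaussians (all sigma pairs), Sobel
gradient magnitude of each smoothed plane, the two Hessian eigenvalue
planes per sigma, and membrane projections (six z-projections — sum,
mean, SD, max, min, median — over a 19 x 3 line kernel rotated in 30
degree steps). A random forest (default 200 trees, sqrt(p) features per
split, single-threaded and seeded, hence bit-reproducible) classifies
pixels into droplet / background by majority vote. Without a model the
package falls back to Yen thresholding of the LD channel — adequate on
clean data, speckle-prone on noisy cytoplasm, and reported as such.

Touching droplets are separated by running the segmented-particles
watershed on the Euclidean distance transform of the LD mask
(prominence 0.5, the binary-image convention), which splits them along
the neck between their distance maxima.

### Mitochondria

Otsu thresholding of the 8-bit mitochondria channel. This assumes the
filament network is bright and abundant enough that Otsu's two-class
split lands between diffuse cytoplasmic signal and the network; a very
dim or sparse network would pull the threshold down.

### Colocalization and contact extraction

A pixel is *colocalized* when three conditions hold simultaneously on
the 8-bit channels:

* LD intensity strictly above the Yen threshold of the LD channel;
* mitochondria intensity strictly above the Otsu threshold of its
  channel;
* the symmetric intensity ratio `100 * min(I_ld, I_mito) / max(I_ld,
  I_mito)` strictly above `ratio_percent` (default 50).

The ratio formula is a declared convention: it is order-independent and
captures "comparable intensity in both channels", which is what close
apposition produces. Raising `ratio_percent` can only shrink the mask
(tested as a monotonicity property).

The colocalization mask is then cut by the LD segmented-particles limit
lines, so a band shared by two droplets is split and attributed to
each. Every region is thinned to a one-pixel 8-connected curve
(Zhang-Suen), and each connected skeleton component is one contact
site. Its length counts traced steps — `s` per orthogonal step,
`s * sqrt(2)` per diagonal step, `s` for an isolated pixel — through a
minimum-spanning-tree traversal of the skeleton pixel adjacencies
(whose total weight is unique even when tie-broken trees are not). No
spur pruning is applied; a branched skeleton contributes its full tree
length. Contacts are assigned to the droplet of their particle region
and to exactly one cell by majority pixel overlap, ties to the lower
label.

### Per-cell measurements

One row per cell: cell area; LD and mitochondria counts, total areas,
perimeters; LD area mean and sample SD (n = 1 gives SD 0 by
convention); contact count, total and mean length; and the *contact
efficiency*, total contact length divided by total LD perimeter — a
normalized measure of how much of the droplet surface is engaged.
Mitochondria are counted as 4-connected components of the mask within
the cell, a declared convention since a fragmented network has no
canonical object count in 2D. Undefined ratios (no LD perimeter) are
NaN, never 0. Organelles overlapping no cell are excluded from per-cell
statistics and reported in a message.

## Numerical conventions

* All auto-thresholds (Otsu, Yen, Huang) operate on 256-bin histograms
  of 8-bit-converted data; foreground is strictly `> t`; ties go to the
  smallest optimizing level. Each implementation is verified for exact
  agreement against an exhaustive brute-force search over all 256
  splits on random histograms.
* 8-bit conversion maps the plane's `[min, max]` linearly onto
  `[0, 255]` with round-half-up; a constant plane maps to zeros; native
  8-bit planes pass through unchanged.
* Median filtering uses the circular kernel
  `{dy^2 + dx^2 <= r^2}` with nearest-edge extension.
* Maxima: 8-connected peak detection; a maximum survives when its
  height above the highest saddle toward strictly higher ground exceeds
  the prominence; plateaus yield one representative, the
  lexicographically smallest `(row, col)` pixel; equal-height maxima
  both survive (neither has higher ground).
* Flooding advances in order of decreasing intensity; *within* one
  intensity level it advances in synchronous breadth-first waves, with
  `(row, col)` ordering inside a wave. Strict global raster ordering of
  ties was considered and rejected: on large plateaus — in particular
  the flat background of a distance transform — raster-ordered fronts
  race across the plateau and place region boundaries far from the
  equidistant ridge. Wave ordering keeps the partition bit-reproducible
  while growing fronts geodesically, so ridge lines fall where the
  geometry says they should.
* Regions are 4-connected complete (every non-limit pixel assigned);
  ridge pixels are 0 in the label map.
* Perimeter is the length of the outer boundary chain traced through
  boundary pixel centres (orthogonal step `s`, diagonal `s * sqrt(2)`;
  single pixel: `4 s`); interior holes do not contribute. The estimator
  is locked by golden tests (a 10 x 10 px square has perimeter 36 px; a
  digitized disk of radius 20 px has chain length 131.88 px against a
  true circumference of 125.66 px — chain codes overestimate smooth
  curves by a few percent, which is acceptable because every comparison
  in the results table uses the same rule).
* Indices are 1-based `(row, col)` throughout, the R matrix convention.

## The synthetic scene generator

Validation needs images whose answers are known. `generate_scene()`
renders calibrated three-channel scenes: elliptical nuclei; disk
droplets of radius 1.0-1.4 um; a mitochondrial network of dilated
random-walk filaments dense enough to pervade the cytoplasm (as a
TOM20-class stain does in 2D projection); and planted contact arcs on
droplet boundaries, rendered as thin annular bands in the mitochondria
channel so that both channels genuinely co-occur there. A Gaussian PSF
(sigma 1.5 px, about 140 nm at the default calibration) is applied,
then Poisson shot noise plus Gaussian read noise, then quantization.

Channel amplitudes are fixed at values chosen for realism once and used
everywhere: background 0.02 of full scale; nucleus 0.85 with a 0.12
cytoplasmic component (weak nucleic-acid staining outside the nucleus,
which supports the flattened cell mask without touching the LD or
mitochondria thresholds); droplets 0.9 over a 0.025 cytosol (the dye is
lipid-specific); filaments 0.8 over 0.05 haze. Contact bands are
rendered at 0.8 with half-width 1 px centred on the droplet boundary,
with rounded end caps of 1.5 half-widths per end. The caps compensate a
known property of thinning — Zhang-Suen erodes the rounded ends of a
band by about its half-width — so that the thinned centreline spans the
planted arc and the analytic ground truth (`radius * dtheta *
pixel_size`) is the right reference. This cap size was calibrated once
on near-noise-free scenes and then frozen.

`snr` is defined as the brightest structure amplitude divided by the
total noise standard deviation at that amplitude; the photon budget is
derived from it. The definition matters when reading results: at
`snr = 5` the peak holds only ~28 photons and cytosolic levels hold
roughly one, so joint Poisson tail events occasionally push a single
cytoplasmic pixel over both channel thresholds and the ratio cut at
once. Each such pixel is, by the method's own definition, a contact of
one pixel. Any component-counting implementation of this workflow shows
the same behaviour on photon-sparse data; it is a property of the
measurement, not a defect of one implementation. Exact contact-*count*
recovery is therefore validated at the generator's realistic operating
point (peak SNR 20, hundreds of photons at peak, typical of fixed-cell
confocal), where the end-to-end suite recovers the planted count
exactly and the total length within 15% on every seeded scene; the
classifier, by contrast, is validated at SNR 5, where it still exceeds
0.85 intersection-over-union against the planted droplets.

What the generator does *not* emulate — and hence what passing tests do
not certify on real data: anisotropic or depth-varying PSFs, uneven
illumination and vignetting, chromatic registration offsets, droplet
clusters in tight contact with each other, autofluorescent debris,
partial-confocality haze from neighbouring sections, and any 3D
structure. Results on real images should be spot-checked against the
label maps the batch runner writes for exactly this reason.

## Validation problem sizes

The shipped test suite validates on: 100 random histograms per
threshold method (exact oracle agreement); 20 random 64 x 64 image
pairs (colocalization pixel-loop oracle); 20 random smooth 56 x 56
landscapes (maxima monotonicity and tiling); 20 seeded 512 x 512
scenes with two cells and six droplets each for end-to-end contact
recovery, with the classifier trained on one independent scene;
scenes with one to five cells for individualization; and one
1024 x 1024 full-frame scene for the single-image runtime check, which
completes in a few seconds on one CPU. These sizes keep the whole suite
in the minutes range while exercising every code path.

## Known limitations

* Contact lengths near the resolution limit are overestimated: a
  sub-pixel contact still produces a >= 1 px skeleton. The original
  comparison of this workflow against electron microscopy reports the
  same direction of bias, for the same physical reasons (projection
  thickness and resolution).
* No skeleton spur pruning: noisy band edges add short branches to the
  traced length. This is deliberate (the behaviour of the reference
  workflow is unspecified) and documented rather than hidden.
* The Yen fallback for LD segmentation speckles on noisy cytoplasm;
  droplet counts from the fallback should not be trusted at low SNR.
  Train a classifier for quantitative work.
* The per-cell "number of mitochondria" is a 2D connected-component
  count, not an organelle count.
* Everything is single-section 2D; no z-stacks or time series.
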