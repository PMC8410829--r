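---
title: "Metastasis segmentation in whole-mouse cryo-images: models and methods"
author: "CryoMetSeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metastasis segmentation in whole-mouse cryo-images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Whole-mouse cryo-imaging sections a frozen specimen and acquires, slice by
slice, co-registered RGB color anatomy and green-fluorescence (GF) volumes
at microscopic resolution (10.472 x 10.472 um in plane, 50 um section
thickness). GFP-labeled metastases appear as bright GF blobs spanning two
orders of magnitude in size, embedded in tissue auto-fluorescence (bone,
bile duct, GI contents, airways, skin/fur) and surrounded by the ivory
embedding cryo-gel. A full-resolution mouse is far larger than RAM, so the
pipeline mixes down-sampled whole-volume processing with chunked
full-resolution processing.

CryoMetSeg implements the complete analysis: candidate generation
(marker-controlled 3D watershed for large bright tumors; per-slice
multi-scale Laplacian-of-Gaussian detection with Otsu segmentation for
small ones), candidate classification (a per-scale 3D CNN ensemble and a
random forest on CNN + hand-crafted features), score-based evaluation,
programmatic correction, and tumor-burden quantification with an
exponential growth model.

# Pipeline stages and their parameters

## Calibration and resampling

Intensities are calibrated per channel by a single linear gain so that a
manually selected pure cryo-gel region hits the standard values (GF 5,
R/G/B 150/120/120). A single reference region admits exactly one degree of
freedom, hence gain-only (no offset); calibration is idempotent. Big-tumor
and exterior steps run on a 40 x 40 x 50 um down-sampling
(`resampleVolume`, linear for intensities, nearest for labels).

## Exterior exclusion

The green channel separates gel from tissue best; voxels with green > 110
are thresholded, 26-connected components are computed, and only components
touching the volume border (within 50% of the largest such component — gel
can be split across the specimen) are gel; bright interior structures such
as bone are thereby retained as body. The gel mask is dilated by an
in-plane disk of radius 2 voxels (80 um) to absorb skin and fur, and the
body is the enclosed complement. The mask shrinks monotonically with the
dilation radius.

## Big-metastases candidates

On the body-masked, down-sampled GF volume: Gaussian smoothing (sigma
160 um per axis, converted to voxels), threshold 20 (pancreatic model: 60),
morphological hole filling with a 400 um ball (closing plus cavity fill),
26-connected components, removal of components < 0.8 mm^3, erosion with a
120 um ball. The survivors are the foreground markers of a
marker-controlled watershed on the 3 x 3 x 3 Prewitt gradient magnitude of
the smoothed volume, with the volume border as the background marker and
26-connectivity. Flooding ties are broken by deterministic insertion order,
so results are reproducible. Fragments mostly outside the body or larger
than 10% of the body are background; the rest are dilated by 0.12 mm and
fragments whose dilations touch are merged into one candidate. The merge
step returns a label volume (not a plain binary mask): two fragments 0.24 mm
apart must count as one candidate, which a binary mask followed by connected
components would undo.

Structuring elements are converted from micrometres to voxels per axis by
rounding to the nearest odd extent, so morphology stays symmetric under the
anisotropic spacing.

## Small-metastases candidates

At full resolution, per z-slice, scale-normalized negative-LoG responses at
sigma = 2, 4, 6, 8, 10 in-plane voxels are maximized across scales
(sigma^2-normalization makes scales comparable). Voxels with response
above T1 (default 10; pancreatic 8) inside the valid region (body minus
up-sampled big candidates) are seeds. Seeds are dilated with the 5-slice
spheroidal element (per-slice disk radii 3, 7, 12, 7, 3); each connected
dilated neighbourhood receives one Otsu threshold of its GF intensities
(overlapping neighbourhoods are processed as their connected union, which
removes order dependence), and above-Otsu voxels form the segmentation. A
constant-intensity neighbourhood keeps its seeds (Otsu is undefined there)
and logs a warning.

Chunking: the volume is split into overlapping slice ranges
(`planChunks`; stride = chunk - overlap, exact pairwise overlap, the last
chunk may be shorter) and per-chunk binaries are merged by voxelwise OR. A
neighbourhood that touches an interior chunk face would see a truncated
intensity histogram and shift its Otsu threshold, so such neighbourhoods
are deferred to the neighbouring chunk; any neighbourhood whose z-extent is
at most `overlap - stride-alignment` slices is then wholly contained in
some chunk, and chunked output equals unchunked output voxel-exactly. The
default overlap is 12 slices, chosen to exceed the tallest z-extent of the
small-candidate operators (5-slice seed element, 5-slice closing); very
tall connected neighbourhoods require a correspondingly larger overlap.

Post-processing removes components 26-connected to the exterior or to big
candidates, applies closing with a 40 x 40 x 200 um box (bridging
inhomogeneous GF signal along z), removes components below 4e6 um^3
(effective sphere radius ~98 um), and unions the survivors with the
up-sampled big candidates into consecutively labeled final candidates that
retain their stage of origin.

## Truth labeling

A candidate is cancer (+) iff its center of mass lies strictly within
60 um (physical distance — spacing is anisotropic) of an annotated tumor's
center of mass, or its modified IoU — intersection over the smaller volume,
tolerant of over-segmentation — exceeds 0.5. One annotation may validate
several over-segmented candidates. With no annotations (a healthy mouse)
every candidate is negative.

## Classification

Each candidate is represented by three two-channel (GF, grayscale anatomy
via Gray = 0.2126 R + 0.7152 G + 0.0722 B; both /255) patches at
neighbourhood sizes 100x100x12, 200x200x24 and 400x400x48 voxels, the
larger two block-averaged to 100x100x12; out-of-volume voxels are zero.

The per-scale 3D CNN has nine "same"-padded convolutions (eight 3x3x3 and
a final 3x3x1) interleaved with three 2x2x2 max-poolings, then global
average pooling, a 256-wide dense feature layer (ReLU) and a 2-class
softmax. The theoretical receptive field, computed by the layer-wise
recurrence r <- r + (k-1) j, j <- j s, is 64 x 64 x 48 voxels, and an
empirical perturbation probe confirms it. Channel widths default to
(32, 64, 128) and are configurable; the 256-wide feature layer and the
receptive field are invariant. Training minimizes class-weighted cross
entropy (weights 1 and 20 by default; the positive weight was searched in
5-30 by step 5) with Adam (batch 8, learning rate 1e-5 by default), 2D
augmentation (zoom 0.9-1.1, rotation -90..90 degrees, flips, brightness
0.8-1.2, one draw applied to all slices and channels), batch-level positive
oversampling (at least 25% positives per batch, drawn with replacement),
and early stopping when the validation loss has not improved for 10 epochs
("did not increase" in the printed description is read as no-improvement
patience, its only self-consistent interpretation); the best-validation
weights are returned. All randomness flows from one seed, so loss
trajectories are bit-reproducible. The three per-scale probabilities can be
fused as p = 0.3 p1 + 0.4 p2 + 0.3 p3, or — the default, better-performing
mode — the three 256-wide feature layers (768 values) are concatenated with
29 hand-crafted features into a random forest.

Hand-crafted features (29): normalized centroid (3); min/max/mean/sd of
color red, color green and GF over the candidate voxels (12); volume,
three principal-axis lengths (from the physical-coordinate covariance,
lengths 2 sqrt(5 lambda)), surface area (face counting scaled by physical
face areas), ZYX Euler angles with a deterministic sign convention, extent,
solidity, equivalent diameter, bounding-box volume and longest/shortest
axis ratio (13); and mean GF per voxel (1). The enumerated feature list in
the source description totals 26; equivalent diameter, bounding-box volume
and the axis ratio pad it to the stated 29. Blue intensities are excluded
to match the stated red/green/GF channel set. Solidity uses per-z-slice 2D
convex hulls (scanline-filled) because no 3D convex hull is available in
the dependency set; for near-spherical candidates this matches 3D solidity.

The random forest defaults are the optimized full-scale settings (752
trees, depth 50, 4 features per split, min 32 at a leaf, min 135 to split,
positive weight 50), mapped onto ranger (num.trees, max.depth, mtry,
min.bucket, min.node.size, class.weights), single-threaded and seeded.
`optimizeHyperparameters` searches the stated ranges (trees 50-1000, depth
1-100, mtry 1-500, leaf 5-150, split 5-150, weight 10-1000) by seeded
uniform sampling, enumerating exhaustively whenever the space fits the
budget of 100 evaluations; the evaluation log is retained. The search
contract (best evaluated point wins) is the interface; a
model-based sampler could be substituted without changing callers.

## Evaluation, correction, burden

`rocAuc` sweeps unique scores (ties grouped), integrates ROC and
precision-recall curves by the trapezoid rule (the PRC is anchored at the
smallest observed recall; this choice is recorded in the output), and
equals the exhaustive pairwise Wilcoxon statistic. `fpAtSensitivity`
reports FP/FN at the largest threshold reaching a target sensitivity.
`kfoldHarness` cross-validates at whole-mouse granularity; the validation
mouse is the remaining dataset with the fewest cancer (+) candidates.
`applyCorrections` is the programmatic replacement for interactive FP/FN
correction and keeps an audit log. `burdenReport` assigns each metastasis
to the organ containing its centroid (mask priority order, warning on
overlap), tabulates counts and 0.5 mm radius histograms — radii are
effective sphere radii, (3V/4pi)^(1/3) — and appends the growth model
N = fraction * V / ((4/3) pi (d/2)^3) with doubling time
t_d = days ln 2 / ln(N/N0) (defaults: 10% cancer cells of 15 um diameter,
1e5 injected, 20 days — the midpoint of the 2-3 week window, consistent
with the printed doubling times). Note that the source text calls the
98 um figure for the 4e6 um^3 sphere a "diameter"; it is that sphere's
radius, and reports here use radii.

# The phantom generator

`generatePhantom` builds the study conditions for every test: a cryo-gel
exterior at the calibration standard; a body ellipsoid (default semi-axes
1200, 1200, 2700 um in a 256 x 256 x 120 desk-scale grid) whose tissue is
dark in green (~80) so the green > 110 rule isolates the gel; an 80 um
skin/fur shell with green ~105 and mildly elevated GF — deliberately below
the gel threshold so that removing it is the job of the 80 um gel
dilation, mirroring the real mechanism; organ masks (lung, liver, brain);
auto-fluorescent confounders with color signatures distinct from tumors (a
bile-duct-like tube, GF +50; two white bone plates, GF +30; ten GI
speckles, GF +50); additive Gaussian noise (sigma 2); and metastases with
log-uniform radii in [50, 1500] um and GF peaks uniform in [120, 220],
white color above 500 um radius.

Metastases are plateau blobs: uniform core to 0.9 r, cosine^2 taper to
zero at 1.25 r (truth voxels are the 1.25 r support). A Gaussian profile
with the nominal radius at two standard deviations was considered and
rejected: its intensity falls to 13.5% of peak at the nominal radius, so
the Otsu-segmented core of a 100-135 um metastasis lands below the 4e6
um^3 filter and the detector would (correctly, per its rules) discard
metastases the size filter is meant to keep. GFP-labeled cell masses have
near-uniform interiors with sharp margins; the plateau profile reflects
that while keeping boundaries smooth enough to exercise Otsu and the
watershed gradient nontrivially.

Placement resamples radius and position on failure (bounded retries), keeps
truth blobs disjoint from each other (and optionally enforces a larger
separation via `minSeparationUm`) and away from confounders (margin =
truncation radius + 250 um) so every candidate has an unambiguous class. A
consequence of the desk-scale body is that metastases above ~600 um rarely
fit, so the watershed path is exercised by dedicated phantoms with a larger
radius range and no confounders; at that body size a single 700 um tumor
occupies ~10% of the body, so those phantom runs raise the fragment-size
cutoff (a parameter whose 10% default mirrors a whole mouse).

What the phantom does not emulate: realistic anatomy and organ texture,
scanner shading or slice-to-slice illumination drift, partial-volume mixing
beyond linear interpolation, the red-fluorescence channel, and spatially
correlated auto-fluorescence. Passing tests therefore demonstrate the
pipeline's contracts (thresholding, morphology, chunking, truth rules,
learning separable candidates), not clinical-grade performance on real
mice; the printed full-scale metrics depend on the real volumes and are
out of reach at desk scale.

# Numerical choices and problem sizes

Gaussian and LoG filters use reflect-101 boundaries; Prewitt uses replicate
boundaries; resampling maps voxel centers and clamps at edges. Otsu uses a
256-bin histogram over the observed range and returns NA on constant input.
Connected components and watershed are deterministic by scan/insertion
order. The CNN runs in single precision (gradient checks against central
differences pass at float tolerance); weight initialization, batch
composition, oversampling and augmentation draw from R's RNG under one
seed. Degenerate cases: single-voxel candidates fall back to voxel
dimensions for axes (solidity and extent 1); pooling floors odd extents;
probabilities are clamped at 1e-7 inside the loss.

Test and verification sizes were chosen to make every contract observable
on one CPU: four default-spec phantoms (256 x 256 x 120) for parameter
recovery with reduced CNN widths (4, 8, 16; the 256-wide feature layer and
the 64 x 64 x 48 receptive field are preserved), shorter training
schedules, and random-forest settings drawn from within the stated search
ranges but suited to tens of candidates (min split 5, min leaf 2, mtry 32,
300 trees) — the full-scale defaults (min split 135) cannot split at all on
desk-scale candidate counts. A 192 x 192 x 80 phantom with four
well-separated 90-120 um metastases drives the chunk-equivalence oracle at
chunk heights 36 and 45 with the default overlap of 12 slices.

# Known limitations

The Otsu threshold of a neighbourhood depends on its full intensity
histogram, so voxel-exact chunk equivalence requires neighbourhoods to fit
inside the chunk overlap; pathological seed chains can exceed any fixed
overlap. Solidity is slice-wise, not a true 3D hull ratio, and differs for
strongly oblique elongated shapes. The merge step's grouped fragments are
reported as one candidate but remain spatially disjoint voxel sets. The
growth model assumes exponential growth at a fixed cancer-cell fraction
and cell size; its outputs are descriptive, not mechanistic. Training the
CNN at the published widths and epochs is computationally heavy in this
implementation (single-threaded BLAS im2col); the architecture is faithful
but throughput-oriented use would swap in a GPU framework behind the same
interfaces.
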