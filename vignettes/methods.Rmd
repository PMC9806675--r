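---
title: "Methods: quantifying endosomal tubulation and codistribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying endosomal tubulation and codistribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoquant)
```

`endoquant` quantifies four families of readouts from calibrated
fluorescence images: per-object shape (roundness, elongation), skeleton
metrics of tubule networks, codistribution statistics between channels, and
3D shortest-distance classification of organelle contacts. This vignette
explains the measurement models, the conventions and tunable parameters,
what the synthetic-scene generator does and does not emulate, and the
numerical choices that make the results reproducible bit for bit.

## Image model and conventions

A `calibrated_image` holds non-negative intensities as `[y, x, channel]`
(2D) or `[y, x, z, channel]` (3D) arrays with a lateral pixel size and,
for stacks, a z step, both in micrometers. The defaults throughout follow
common confocal practice for this kind of data: 0.07 µm pixels and 0.08 µm
z steps. A pixel's physical position is its **center**; rasterization marks
a pixel foreground iff its center lies inside the analytic shape, and all
distances are measured center to center. This one convention is used by the
generator, the measurements, and the brute-force oracles in the test suite,
which is what lets the oracle-equivalence tests demand exact agreement
(tolerance 1e-9) rather than "close enough".

On disk, images are integer TIFF pages (16-bit by default) plus a JSON
sidecar carrying channel names and calibration; the installed TIFF writer
exposes neither resolution tags nor description fields, so the sidecar is
authoritative, followed by TIFF resolution tags when reading foreign files,
followed by an explicit override (which wins over a conflicting sidecar,
with a warning). Intensities are returned as floating point without
rescaling; round-trips are exact for integer-valued data within the bit
depth, and non-integer data are quantized to the integer grid with a
warning.

## Morphometry

Two shape metrics characterize vesicle morphology:

* **Roundness** (%) = `100 · r_in / r_enc`, where `r_in` is the radius of
  the largest circle inscribed in the object and `r_enc` the radius of the
  smallest circle enclosing it. We read the ratio this way around — largest
  inscribed over smallest enclosing — because it is the only normalized
  reading that yields a percentage bounded by 100, with 100 for a disk,
  ~50 for a 2:1 ellipse and ~71 for a square.
* **Elongation** (≥ 1) = `d1 / d2`, the axis-diameter ratio of the ellipse
  with the same normalized second central moments as the region; a
  non-elongated object has the minimal value 1.

`r_in` is the maximum over foreground pixel centers of the distance to the
nearest background pixel center, computed by an exact Euclidean distance
transform; `r_enc` is the minimum enclosing circle of the foreground pixel
centers (convex hull, then Welzl's algorithm with a fixed deterministic
insertion order, so no RNG state is touched). Second moments add 1/12 per
axis, treating each pixel as a unit square; this makes an L×W rectangle
measure exactly L/W and means a 1-px-wide line of L pixels measures L
rather than a degenerate infinity (an `Inf` branch with a warning remains
as a numerical guard). Degenerate single-pixel objects are defined to have
roundness 100 and elongation 1, the limiting behavior of a point. Interior
holes are filled before the inscribed radius is computed — an annulus
otherwise gets a spuriously tiny inscribed circle — and the per-image
summary reports both mean and median aggregations, since per-cell
aggregation conventions differ between labs.

Rasterization error of these metrics falls below 5 % once the semi-minor
axis reaches about 10 px; the default synthetic vesicles (semi-minor
0.25–0.45 µm ≈ 4–6 px, realistic for early endosomes) sit below that, so
recovery tests that assert 5 % accuracy use enlarged vesicles
(0.8–1.1 µm), while tests on the default scene assert object counts and
support masks exactly.

## Tubule networks

Tubule masks are thinned with the Zhang–Suen algorithm to an 8-connected,
1-px-wide skeleton, which is collapsed into a graph: node pixels are those
with ≠ 2 skeleton neighbors, adjacent node pixels cluster into a single
node (a thinned 3-way junction is often 2–3 adjacent pixels; it must count
once), and maximal degree-2 chains become edges. Three cleaning rules deal
with thinning artifacts:

* endpoint-terminated edges shorter than `prune_spur_um` (default 0.25 µm,
  3–4 px) hanging off a junction are pruned as whiskers;
* closed loops shorter than twice that threshold at a junction or blunt end
  (a known thinning artifact) are removed;
* nodes left with degree 2 are merged away, re-joining their edges.

**Edge length.** The naive chain-code length (1 or √2 px per step)
overestimates oblique straight lines by up to ~8 % (worst at 22.5°), which
would violate the 5 % length-recovery target for randomly oriented tubules.
The default estimator therefore measures a polygonal resampling of the
skeleton path (every 4th pixel), accurate to ~1–2 % for smooth tubules;
the chain-code value is kept alongside as `length_chain_um`. Thinning also
erodes about one tube radius from each rounded tip, so when the source mask
is supplied, each free end is extended by the local half-width (the
distance transform of the mask at the endpoint pixel) — a measurement-side
correction using only the observed mask.

A **triple connection** is a junction node; a degree-4 node still counts
once (what is scored visually is a 3-way connection; higher orders are not
distinguished), with `weighting = "excess_degree"` available. A **tubule**
is a maximal connected component of the graph with total length ≥
`min_length_um` (default 0.5 µm — manual inclusion criteria are never
published, so the cutoff is explicit and logged). Counts are normalized per
100 µm² and junctions per 50 µm² via `per_area()`; the ROI area defaults to
the full field and should be the cell area when ROIs are supplied.

## Codistribution

Codistribution fractions are computed on binary mask areas — matching the
mask-based workflow they mechanize — with an intensity-weighted variant as
an option. `overlap_fraction(A, B)` = `100·|A∩B|/|A|` is deliberately
asymmetric; `merge_percentage` is symmetric and defaults to the union
denominator `|A∪B|`, with the `|A|+|B|` reading selectable and the choice
recorded in the result's `denominator` attribute, since "total fluorescence
of both channels" admits either reading.

Spot detection is a single-scale difference of Gaussians (σ and 1.6 σ)
followed by 3×3 local maxima, thresholded at median + k·MAD of the response
(k = 5) for noise stability, floored at 10 % of the peak response so that
noiseless images (MAD = 0) behave; adjacent maxima collapse into one spot
at their response-weighted centroid. Association percentages count spots
whose centroid lies within `radius_um` of reference foreground (default 0:
the centroid's pixel must touch the mask) or of a reference spot centroid
(default: the reference spot radius); association is non-decreasing in the
radius by construction.

## Along-tubule paired enrichment

For each tubule a polyline is supplied (hand-drawn ROI or a skeleton edge
path) and all channels are sampled by bilinear interpolation at equal
arclength steps (default: the pixel size; positions are arclength, which
coincides with pixel index for straight lines). The paired statistic takes
the arclength of the reference channel's maximum (ref+) and minimum (ref−),
reads the target channel at those positions, and subtracts the minimal
target intensity of the profile from both readings, guaranteeing
non-negative values and invariance to constant target offsets. Ties in the
extrema break toward the smallest arclength, for determinism. Profiles are
unsmoothed by default; a 3-sample moving average mirroring plot-plugin
behavior can be enabled. Cohorts are summarized by per-tubule differences
and a two-sided paired t test, with explicit conventions for degenerate
cohorts: all-zero differences give t = 0, p = 1; nonzero zero-variance
differences are flagged rather than tested.

Two properties matter for interpretation. First, a punctum narrower than a
couple of pixels is attenuated by pixel sampling and interpolation, and PSF
blur attenuates sub-resolution peak amplitudes substantially (a σ = 0.15 µm
punctum blurred by a σ = 0.1 µm PSF keeps only ~70 % of its peak); the
statistic reads intensities as imaged and does not deconvolve. The
generator therefore plants punctum amplitudes as on-grid peak intensities,
and the statistic-calibration experiments use shot and read noise with blur
disabled, isolating the estimator from the optics. Second, the null
(independent channels) is only centered when the reference channel has a
positive background: with a zero background, zero-clipped noise pins the
profile minimum to the profile start and biases the pair — the simulator
defaults to a background of 10 for exactly this reason.

Calibration results computed by the test suite: over 500 simulated null
cohorts (20 tubules each) the paired test rejects at a rate inside
[0.03, 0.07] at α = 0.05, and with full colocalization the planted
enrichment δ is recovered within 2 standard errors over a 20-tubule cohort.

## 3D proximity classification

Distances between labeled 3D objects and reference masks are shortest
center-to-center distances under anisotropic voxel spacing, computed by an
exact Euclidean distance transform (sequential 1D lower-envelope passes,
with per-axis spacing; a small compiled kernel) of the reference mask,
sampled at the object's voxels; overlap gives 0. This agrees with
brute-force all-pairs voxel distances to floating-point precision and
approximates mesh-based surface distances within half a voxel. An object
within `d_max` of both the ER mask and the marker mask is a **triple
codistribution event**; the percentage over all objects and the density per
100 µm² of projected ROI area are reported. `d_max` has no published
value in the workflows this mechanizes; it is a required, logged parameter,
with 0.2 µm (≈ lateral confocal resolution, the scale of light-microscopy
contact detection) as the suggested default. Marker variants (different
proteins) are the same code path with a different channel.

## The synthetic scene generator

The generator is the package's ground-truth oracle; its defaults are the
study conditions under which every statistic is validated.

* **Vesicle fields**: non-overlapping ellipses (rejection sampling with a
  1000-try cap, then an explicit infeasible-packing error), round ones in
  the EEA1 role, elongated ones (aspect 1.8–3.5, semi-minor 0.25–0.45 µm)
  carrying both channels so the planted mask overlap is nontrivial. Truth
  records per-object roundness `100·b/a` and elongation `a/b`.
* **Tubule scenes**: smooth random polylines (0.25 µm steps with angular
  jitter, steered away from field borders), tube radius 0.12 µm, lengths
  N(10, 2²) µm, mutually separated so masks do not merge; side branches
  attach at 60–110° and are the planted 3-way junctions. Reference puncta
  (3 per tubule, ≥ 0.6 µm apart, amplitudes 100·U(0.8, 1.25)) and target
  puncta (baseline 40 along the tubule, amplitude δ = 60 at colocalized
  sites with probability ρ; non-colocalized puncta fall uniformly and
  independently, since independence is what ρ = 0 means).
* **3D ER scenes**: a connected meshwork grown by anchoring each new
  segment on the existing structure until the target volume fraction
  (default 4 %) is reached, at 0.07/0.08 µm voxels; markers on ER voxels
  ≥ 0.7 µm apart; endosomes (r = 0.18 µm) either overlapping a
  marker-bearing locus (distance 0 by construction; each attached endosome
  needs its own marker) or placed on the iso-distance shell of the ER
  distance map at a planted gap (realized within grid quantization,
  ±0.1 µm, and verified before acceptance).

Noise follows the standard camera model: PSF blur (Gaussian, lateral,
applied slice-wise in 3D), plus background (default 10), Poisson shot
noise (gain 1), Gaussian read noise (SD 2), clipped at zero; `gain = 0`
and `psf_sigma = 0` disable the respective components, and `noise_none()`
gives the noiseless regime in which rasterized support equals the truth
mask exactly. One integer seed drives a named per-scene stream
(`derive_seed`), so identical calls are bit-identical and adding a stage
never perturbs another's stream.

What the generator does **not** emulate: realistic optics (no Airy or
depth-dependent PSF, no axial blur), photobleaching, motion, spectral
bleed-through, uneven illumination, or the irregular texture of real
membranes. Passing recovery tests on these scenes therefore demonstrates
correctness of the measurements under the stated model, not performance on
real micrographs; on real data the thresholding stand-in below is the main
caveat.

## Segmentation stand-in

The workflows this package mechanizes select signal with an interactively
trained pixel classifier before mask conversion. That step is inherently
training-data-dependent, so `endoquant` substitutes global Otsu or fixed
thresholding plus a minimum object size (4 px in 2D, 8 in 3D, suppressing
shot-noise speckle), with 8/26-connectivity labeling by default
(tubule-preserving; 4/6 available). This is sufficient for synthetic
scenes — on noiseless two-level images Otsu recovers the support exactly —
and is documented as a stand-in, not a reimplementation, of
classifier-based selection; no shape-prior curation beyond the size filter
is applied.

## Pipeline, determinism and problem sizes

`run_pipeline()` executes configured stages with stage-local seeds derived
from one master seed, echoes every resolved parameter into a run log, and
stamps outputs with a hash of the analysis-relevant configuration (the
output directory is excluded from the hash, so identical analyses into
different directories produce byte-identical CSVs). The starved-vs-control
demonstration plants more elongated vesicles and more, longer, more
branched tubules in the starved condition; across 100 seeded replicates
every planted effect direction is recovered in ≥ 95 % of runs.

Validation problem sizes, chosen to exercise each property at meaningful
statistics while keeping the whole suite within a few minutes: 100 random
blobs (≤ 200 px) for circle-oracle equivalence; 20 noise-free plus 20
noisy tubule scenes (5 tubules, 3 branches each) for network recovery;
500 null cohorts of 20 tubules for test calibration; a 12-endosome 3D
scene checked voxel-by-voxel against brute force; 100 demo replicates for
effect signs.

## Known limitations

* Thresholding is a stand-in for trained pixel classification; on real,
  textured data the masks (and everything downstream) will differ.
* 2D morphometry only; the roundness/elongation readouts are defined on
  projections, not volumes, and skeletonization is 2D (stacks are
  max-projected first).
* The enrichment statistic uses one max/min pair per tubule; multi-peak
  structure along a tubule is not modeled.
* Voxel-grid distances approximate surface distances within half a voxel;
  no meshing is performed.
* Chain-code and resampled length estimators disagree by a few percent on
  very short (< 5 px) edges, where the resampler falls back to chain code.
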