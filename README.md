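# endoquant

Quantitative image analysis of endosomal morphology, tubule networks and
organelle codistribution in fluorescence microscopy.

When autophagy is induced (e.g. by starvation), early endosomes change
shape: round EEA1-positive vesicles elongate, SNX1-decorated membranes emit
branching tubules, and SNX1 structures appear next to ER subdomains where
autophagosomes assemble. Quantifying those phenotypes from micrographs
requires a small zoo of measurements that are usually spread across several
interactive tools. `endoquant` implements them as one tested, scriptable R
package, for cell biologists and image analysts who want reproducible
numbers instead of point-and-click readouts:

* **Morphometry** — per-object *roundness*,
  `100 · r_inscribed / r_enclosing` (the largest circle that fits inside
  the object over the smallest circle containing it, in percent), and
  *elongation*, `d1/d2 ≥ 1`, the diameter ratio of the ellipse with the
  same normalized second central moments (1 for a disk). Both radii are
  computed with pixel-center arithmetic and verified against brute-force
  enumeration.
* **Tubule networks** — Zhang–Suen skeletonization, a node/edge skeleton
  graph with spur pruning, tubule counts per 100 µm², per-tubule lengths in
  µm, and *triple connections* (3-way junctions) per 50 µm².
* **Codistribution** — binary-mask overlap fractions (`100·|A∩B|/|A|`),
  merged-signal percentages (`100·|A∩B|/|A∪B|`), difference-of-Gaussian
  spot detection, and spot–signal association percentages.
* **Along-tubule enrichment** — multi-channel intensity profiles along a
  tubule polyline and the paired statistic: the target-channel intensity at
  the arclength where the reference channel is highest (ref+) versus lowest
  (ref−), each minus the profile's minimal target intensity, summarized by
  a two-sided paired t test.
* **3D proximity** — exact anisotropic Euclidean distance transforms,
  shortest object–surface distances in µm, and classification of triple
  codistribution events (within `d_max` of both an ER mask and a marker
  mask), reported as a percentage and per 100 µm².
* **Synthetic scenes** — a ground-truthed generator of vesicle fields,
  branched tubule scenes with puncta, and 3D ER/marker/endosome stacks
  under a Poisson + Gaussian camera model with Gaussian PSF blur. Every
  statistic above is validated against the generator's planted parameters.

## Worked example

```r
library(endoquant)

# a synthetic starvation-like field with known ground truth
scene <- make_vesicle_scene(n_round = 8, n_elongated = 6, seed = 42)
img <- scene$image
img
#> <calibrated_image 2D> 214 x 214 px, 2 channel(s)
#>   pixel: 0.07 um
#>   channels: EEA1, SNX1

morph <- measure_all(label(binarize(img, "EEA1")), img$pixel_size_xy)
head(morph[, c("label", "area_um2", "roundness_pct", "elongation")], 4)
#>   label area_um2 roundness_pct elongation
#> 1     1    0.554          58.6       1.75
#> 2     2    0.735          59.0       1.76
#> 3     3    1.529          33.8       3.19
#> 4     4    0.524          92.5       1.10
attr(morph, "summary")
#>          metric  mean median     sd  n
#> 1 roundness_pct 74.92  88.94 24.118 14
#> 2    elongation  1.55   1.12  0.661 14
```

Round vesicles score roundness near 100 % and elongation near 1; elongated
vesicles (planted aspect ratios 1.8–3.5) pull the mean elongation to 1.55.
Tubule networks go through the skeleton graph:

```r
ts <- make_tubule_scene(n_tubules = 5, branch_count = 3, seed = 42)
tmask <- binarize(ts$image, "SNX1")
graph <- build_graph(skeletonize(tmask), ts$image$pixel_size_xy, mask = tmask)
measure_tubules(graph)
#> <tubule_metrics> 5 tubules (2.55 per 100 um^2), 3 junctions
#>   lengths (um): 13.16, 10.07, 9.76, 8.75, 8.59
count_triple_connections(graph)$count
#> [1] 3
```

All 5 planted tubules and all 3 planted branch junctions are recovered at
the default acquisition noise. `demo_pipeline(seed = 1)` runs the full
starved-versus-control demonstration and writes per-stage CSVs, a JSON
summary and a run log; `inst/scripts/endoquant-cli.R` wraps the same
functions for shell use.

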