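---
title: "Methods: Sholl-based astrocyte morphometry and profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Sholl-based astrocyte morphometry and profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astromorph)
```

# Scope and model

`astromorph` quantifies the morphology of single immunolabeled astrocytes
in calibrated 2D micrographs and stratifies cohorts of cells into six
recurrent morphometric profiles. The analysis object is the visible,
GFAP-labeled part of a cell in a thin (4–5 µm) section: an intermediate-
filament-rich soma plus the larger processes. Everything downstream —
skeletons, Sholl counts, territory estimates — describes that visible 2D
profile, not the complete three-dimensional astrocyte domain (GFAP labels
only a minor fraction of the true arbor volume). A green test therefore
establishes correctness of the *measurement chain*, never biological
completeness of the measurement.

The chain per cell is:

1. **Segmentation.** Foreground by Otsu's threshold (or a fixed value);
   optional distance-transform watershed to split touching cells; the
   connected component containing (or nearest to) the image center is the
   cell. Coordinates are (row, col), 1-based, origin top-left, everywhere.
2. **Gap closing (optional).** Sectioning can interrupt a process.
   Endpoint pairs of distinct fragments that lie within `max_gap` px and
   whose local orientations are near-collinear with the connecting segment
   are bridged by a 1-px line. Only such bridges are ever added — no
   branch is created de novo — and the operation never removes foreground
   nor increases the number of connected components. `max_gap = 0`
   (default) disables it.
3. **Soma/process separation.** The soma is the connected core surviving
   morphological opening with the largest Euclidean-disc radius whose
   opening still covers the soma seed (a user hint, or the center of the
   maximal inscribed disc). The original workflow placed the soma center
   manually; the algorithmic default makes runs reproducible, and the hint
   preserves fidelity when a manual center exists. Degenerate cases (core
   radius < 2 px, e.g. a hint inside a thin process) fall back to the
   maximal inscribed disc; a cell with no resolvable core is an error.
4. **Skeletonization.** Zhang–Suen thinning of the process mask (soma
   removed, so rings overlapping the soma cannot inflate proximal counts),
   followed by pruning of terminal spurs shorter than 4 px — a standard
   guard against thinning artifacts of thick limbs; whole components are
   never pruned. Endpoints have exactly one skeleton 8-neighbor, branch
   points three or more.
5. **Sholl profiling.** Concentric rings centered on the soma centroid at
   a constant increment (default 10 px), counted in two modes: `pixel`
   (skeleton pixels on the ring — the default, matching intersection
   totals in the thousands) and `run` (crossing clusters — the classical
   count).
6. **Six metrics** (see below), cohort stratification by pooled medians,
   and the nonparametric statistical scheme.

# Numerical choices that matter

**Ring digitization.** Rings use grid-intersection (supercover)
digitization: a pixel belongs to the ring when the true circle intersects
its closed unit square. This yields a closed, 4-connected digital curve,
and by the digital Jordan property an 8-connected skeleton path from
inside to outside *must* share a pixel with it. The naive 8-connected
midpoint circle does not have this property — a skeleton can slip
diagonally through it, silently losing crossings at some arm angles. The
radius-1 ring has 8 pixels under this dialect.

**Run-mode crossings are clusters.** One transversal crossing of a digital
curve over a digital ring can deposit on-ring pixels separated by a 2-px
Chebyshev gap (the curve dips between two diagonally adjacent ring
pixels). Run mode therefore merges on-ring pixels within Chebyshev
distance 2 into one crossing. Pixel-mode counts are unaffected, and the
run ≤ pixel dominance holds per ring by construction.

**Primary processes and terminals.** A primary process is one 8-connected
cluster of skeleton pixels adjacent to the soma; since thinning retracts a
blunt stub by up to ~3 px from the soma boundary, "adjacent" is
operationalized as within 3.5 px of the soma mask. Terminal endings are
skeleton endpoints that are neither soma-adjacent nor on the image border
(border endpoints are truncated processes, excluded). A cell with zero
primaries has an undefined terminal-to-primary ratio and raises an error;
the pipeline logs and excludes such cells, mirroring the quality
exclusions applied to sectioning-artifact cells.

**Soma boundary slack.** A pure Euclidean opening clips the staircase
boundary of a rasterized soma — harmless at native resolution, but after
nearest-neighbor ROI enlargement the staircase steps grow with the scale
factor and the clipped ring costs several percent of soma area. The opened
core is therefore dilated by `radius + slack` (clipped to the cell mask),
with slack equal to the ROI scale factor (1 for native images). Measured
on disc phantoms, soma area then agrees across scale factors 1, 2 and 4 to
within 0.2%.

**Quantization of ring-derived metrics.** The maximum process length and
the territory radius are read off the last intersecting ring, so they are
quantized to the ring increment; no interpolation beyond the last ring is
performed (the source workflow does not state any). The increment is a
pixel quantity: cross-scale physical invariance of these two metrics
therefore requires scaling the increment with the ROI; soma area is
invariant without qualification.

**Two origins, kept distinct.** Maximum process length is measured from
the soma *outline*; the territory radius from the soma *center*. These are
deliberately not reconciled — fidelity to the stated definitions over
internal consistency — so `territory ≥ π(length/2)²` is *not* an
invariant, and tests assert only the weaker bound that accounts for the
soma radius and one ring interval.

**Tie and ordering rules.** Binarization against the global median sends
ties *below* (small cohorts frequently have observations equal to the
median). The targeted post hoc reference on a tie in
|profile median − global median| is the lower profile id, flagged in the
output. Percentiles everywhere use linear interpolation (R type 7), and
the rule is printed in reports because tool defaults differ.

**Profiles 4 and 6.** Both are process-dominant with below-median soma and
share one above/below pattern; the source distinguishes them only
qualitatively (dense, symmetric branching vs long radial extension). The
package separates them by a single documented, swappable rule: within the
cohort, a cell whose total-intersection percentile rank exceeds its
max-process-length percentile rank is profile 4, otherwise 6; the
`disambiguator_used` flag marks every assignment that needed it. Patterns
matching no signature are reported `unclassified`, never forced to the
nearest profile.

# Statistics

Between-group and between-profile comparisons use the tie-corrected
Kruskal–Wallis statistic referred to χ² with k−1 degrees of freedom; when
the pooled sample has at most 10 observations the exact permutation null
(all distinct assignments to groups of the observed sizes) is enumerated
instead — at those sizes the χ² approximation is poor and enumeration is
cheap. All observations tied defines H = 0, p = 1.

Post hoc comparisons follow the targeted design: for each parameter,
every profile is compared only against the profile whose median is closest
to the global median (a reference near the cohort's central tendency,
avoiding the multiplicity of all pairwise tests). The pairwise statistic
is the two-sample rank-sum test (normal approximation with tie and
continuity correction); the source names only the omnibus test and the
correction, so this choice is documented and isolated. Raw p-values are
corrected by the Benjamini–Krieger–Yekutieli two-stage adaptive step-up:
stage 1 runs a linear step-up at α′ = α/(1+α) to estimate the number of
true nulls m₀ = m − r₁; stage 2 reruns the step-up at α′·m/m₀. Reported
q-values satisfy reject ⇔ q ≤ α. The procedure provably rejects a superset
of plain Benjamini–Hochberg when r₁ > 0, and decisions are monotone in
each p-value — both are checked empirically in the test suite against an
independent, literal implementation of the definition.

α defaults to 0.05. Density statistics use the per-case cumulative count
over the counting fields (10 fields of 0.159 mm² per case by default) as
the statistical unit; the per-field distribution is retained.

# The synthetic world

Phantoms are drawn directly as rasters and all truths are computed from
the same construction, so recovery tests are exact by design:

* **Star astrocytes** — a filled-disc soma (radius ≥ 1 px) with arms
  leaving the soma outline at equally spaced angles, optional angular
  jitter (a fraction of the inter-arm spacing), optional symmetric
  bifurcations (children shrink by 0.6 per generation, ±20° of the parent
  direction). Arms are 1-px Bresenham polylines by default: a 1-px curve
  is its own skeleton, which keeps endpoint/branch truth exact; 2–3 px
  thicknesses are available to exercise thinning robustness instead.
  Intensities follow a DAB-like two-level model (foreground 200,
  background 30 on the 8-bit scale, Gaussian noise sd = 10·jitter),
  exercising Otsu nontrivially; binary output is available.
* **Counting fields** — n cells placed uniformly with a minimum pairwise
  center separation and bounded retries (explicit error when placement is
  infeasible). The default field is the study's 0.159 mm² at 1.0 µm/px
  (≈ 399 px side): the source states no calibration, and a finer default
  would quadruple the raster for no counting benefit; single-cell phantoms
  default to 0.25 µm/px, the documented stand-in calibration.
* **Metric cohorts** — six-metric vectors drawn per profile from
  log-normal distributions whose medians are the published per-profile
  medians. Unpublished centers are imputed: the length-to-soma ratio of
  profiles 1–3 from the published length and soma medians (the resulting
  ratios fall on the correct side of the global median), all others as
  0.8× / 1.25× the global median according to the profile's signature,
  flagged via the `imputed` attribute. The default within-profile spread
  (σ = 0.15 on the log scale) is a mild, realistic overlap; σ = 0
  reproduces the printed medians exactly. These vectors are statistical
  stand-ins — six independent draws, not a geometrically consistent cell.

What the phantoms do **not** emulate: DAB/hematoxylin color and staining
gradients, out-of-focus light, overlapping arbors, 3D sectioning effects,
and hand-annotation variability. Consequently a green suite certifies the
geometry, counting, and statistics of the pipeline — not its performance
on stained tissue.

One boundary effect is worth knowing: on a *balanced* zero-noise cohort
(equal cells per profile) the pooled soma median lands below profile 1's
printed median (115.1 µm² vs the published global 118.8 µm²), flipping one
bit of profile 1's pattern. Recovery of generating profiles is therefore
asserted against the published global medians (the `medians` argument of
`profile_cohort()`); with cohort-derived medians the assignment is exact
for all profiles except that documented boundary case.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `microns_per_px` | 0.25 µm/px | calibration; required for real data, default documented as a stand-in |
| `interval` | 10 px | Sholl ring spacing (the source's fixed increment) |
| `mode` | `"pixel"` | intersection counting; `"run"` is the classical crossing count |
| `threshold` | `"otsu"` | or a fixed numeric threshold |
| `max_gap` | 0 px | endpoint bridge limit for gap closing |
| `prune_px` | 4 px | spur-pruning threshold after thinning |
| `fields_per_case` / `field_area` | 10 / 0.159 mm² | counting design |
| `min_object_area` | 20 µm² | smallest counted object in fields |
| `alpha` | 0.05 | FDR level |
| `seed` | — | all randomness flows from it; same seed ⇒ identical outputs |

# Known limitations

* 2D only; no convex-hull or 3D territory estimation, no Sholl regression
  metrics (decay, ramification index) — the source reports none of these.
* The watershed separator uses plateau markers of the distance transform;
  heavily overlapping cells with shallow necks may not split.
* Gap closing is endpoint-based; it cannot reconnect fragments whose break
  is wider than `max_gap` or strongly curved.
* The soma separation automates a manual step; on real material the
  optional hint should be used when a manual center is available.
* With intensity noise far beyond the phantom model (sd ≫ 10), Otsu's
  threshold and the speck filter (`min_object_area`) interact; field
  counting accuracy is only certified within the stated noise model.
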