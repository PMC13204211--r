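# astromorph

Sholl-based morphometry and profiling of GFAP-labeled astrocytes in 2D
histology images.

## The problem

Astrocytes visualized by GFAP immunohistochemistry vary enormously in shape:
soma size, number and length of processes, branching density, and the
territory a cell's arbor spans. Quantifying that heterogeneity from routine
2D DAB-stained sections requires a reproducible chain of image operations —
segment the cell, separate soma from processes, skeletonize, count
intersections with concentric Sholl rings — followed by a defensible
statistical treatment of the resulting descriptors. `astromorph` implements
that chain end to end for single-cell regions of interest and for
cell-density counting fields, together with a synthetic-phantom generator so
that every stage is testable against exact ground truth without tissue data.

## The method

For each cell the package computes six descriptors:

| metric | definition | units |
|---|---|---|
| maximum process length | distance from the soma outline to the most distal skeleton pixel on the last intersecting Sholl ring | µm |
| total intersections | Sholl counts summed over all rings (pixel-crossing mode by default; classical run/crossing mode available) | count |
| terminal-to-primary branch ratio | terminal skeleton endpoints ÷ soma-originating primary processes | — |
| soma size | segmented soma area | µm² |
| length-to-soma ratio | max process length ÷ soma area | µm⁻¹ |
| territory size | π·r², r = last Sholl intersection radius from the soma center | µm² |

Sholl rings are digitized with the grid-intersection (supercover) rule at a
constant radial increment (10 px by default), which makes the digital ring a
closed 4-connected curve: an 8-connected skeleton cannot cross it without
intersecting it, so crossing counts are sound at every arm angle.

A cohort of cells is stratified by its pooled per-metric medians: each cell
becomes a six-symbol above/below pattern that is looked up in the signature
table of six recurrent morphometric profiles (compact low-arbor,
soma-dominant, large-soma/large-arbor, process-dominant dense,
smallest-soma, process-dominant long-reach). Group and profile comparisons
use the tie-corrected Kruskal–Wallis test (exact permutation null for
pooled n ≤ 10), targeted post hoc rank-sum comparisons against the profile
whose median is closest to the global median, and the
Benjamini–Krieger–Yekutieli two-stage FDR procedure.

## Worked example

Measure a synthetic astrocyte phantom — a 12 px soma with five
once-bifurcating arms (ground truth: 10 terminals / 5 primaries = 2.0):

```r
library(astromorph)
spec <- phantom_spec(soma_radius = 12, n_primaries = 5, arm_length = 60,
                     branch_depth = 1, jitter = 0.3, seed = 42)
ph <- make_star_astrocyte(spec)
mv <- measure_cell(ph$image, interval = 10, mode = "run")
mv[, metric_names()]
#>   max_process_length total_intersections terminal_primary_ratio soma_size
#> 1           22.12041                  60                      2    27.875
#>   length_soma_ratio territory_size
#> 1         0.7935573       1963.495
```

The ratio is exactly 2, the soma is 446 px × (0.25 µm)² = 27.9 µm², and the
territory radius √(1963.5/π) = 25 µm is the last ring (100 px) at the
default 0.25 µm/px calibration.

Stratify a synthetic 36-cell cohort (6 per profile, log-normal spread
around the published per-profile medians) and run the statistics:

```r
coh  <- make_metric_cohort(setNames(rep(6, 6), 1:6), seed = 1, sigma = 0.15)
prof <- profile_cohort(coh)
attr(prof, "global_medians")
#> <global_medians> n = 36 cells
#>   max_process_length           30.5 (IQR 20.6-36.8)
#>   total_intersections      2.18e+03 (IQR 998-3.2e+03)
#>   terminal_primary_ratio       1.75 (IQR 1.55-2.13)
#>   soma_size                     121 (IQR 98.5-193)
#>   length_soma_ratio           0.241 (IQR 0.164-0.433)
#>   territory_size                292 (IQR 220-379)
table(assigned = prof$profile_id, useNA = "ifany")
#>    1    2    3    4    5    6 <NA>
#>    1    7    5    5    3    4   11
compare_profiles(prof)$soma_size
#> <group_comparison> [soma_size] KW H = 20.365, df = 5, p = 0.001067 (chi-square)
#>   reference: 1 (median 104.2, global 116.9) ...
```

With 15% noise, 25/36 cells land exactly on a signature pattern; patterns
matching no signature are reported as unclassified rather than forced into
a nearest profile, and soma size still separates the profiles strongly
(KW p ≈ 0.001).

## Command line

```sh
inst/cli/astromorph simulate --out sim --n-cells 12 --n-fields 4 --seed 1
inst/cli/astromorph run-all  --manifest sim/manifest.csv --out results --seed 1
```

`run-all` emits per-cell metrics, profile assignments, per-case density
counts, a statistics report (CSV + JSON), and a run log; identical
config + seed gives byte-identical CSVs. Subcommands `segment`, `sholl`,
`metrics`, `profile`, and `stats` expose the individual stages.

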