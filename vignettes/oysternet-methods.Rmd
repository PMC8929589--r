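---
title: "Methods: indices, dispersal networks, and substrate selection in oysternet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: indices, dispersal networks, and substrate selection in oysternet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oysternet)
library(dplyr)
```

## The problem

Conserving a coastal foundation species requires knowing where it is, where
it was, and how connected its remaining populations are. `oysternet`
implements a record-based workflow for two intertidal oysters of the North
American Pacific coast — the native Olympia oyster (*Ostrea lurida*) and the
non-native Pacific oyster (*Magallana gigas*) — in which the unit of
observation is a *site record*: a point at the center of a 20-m stretch of
low intertidal shoreline, scored on a coarse abundance scale (common = more
than 100 living oysters, rare = 1–100, present with unknown abundance, or
absent), with a year, a substrate class, and a source type.

Three analyses are built on these records:

1. **Per-estuary indices and temporal change.** For each estuary, species,
   and period (pre-2000 vs the current window 2000–2020), the
   *distribution index* is the fraction of records with the species present
   (presence + absence in the denominator) and the *abundance index* is the
   fraction of abundance-informative records scored common (common + rare
   in the denominator; merely-"present" records carry no abundance
   information and are excluded). Change is tested with a paired Wilcoxon
   signed-rank test using each estuary as a replicate, restricted to
   estuaries with at least three records in both periods.
2. **Larval and adult dispersal networks.** Sites occupied in 2000–2020 and
   within 30 km of each other *along water* (not as the crow flies) belong
   to the same larval network. Along-water distance is computed on a
   rasterized land/water grid with the coastline acting as a barrier. Each
   network's polygon is the union of its members' 30-km reachable water
   zones; the adult network is the part of that polygon inside estuary
   boundaries. Connectivity is the shortest along-water distance between
   network polygons, and isolation is the mean distance to the nearest
   network to the north and to the south.
3. **Substrate use and selection.** Presence records from 2000–2020 are
   tabulated over six substrate classes (riprap/boulder, cobble,
   gravel/pebble, sandflat/mudflat, seawall/dock/piling, other
   anthropogenic structure), compared across regions and species by
   chi-square (regions with any class below 5 observations are dropped),
   and compared with availability through the selection index
   $w_i = u_i / p_i$ with a simultaneous confidence-interval
   preference/avoidance rule.

## Data model and classification rules

Records are plain tibbles with a documented column dictionary; readers
normalize enum tokens case-insensitively through a published synonym table
(`normalize_enum()`) and reject rows violating the schema (years outside
1602 to the current year, non-finite coordinates, unknown tokens, duplicate
ids) with row-level diagnostics. All analysis coordinates are planar meters
in an equal-area frame, because distances and areas are the currency of
every downstream computation; geographic latitude/longitude are carried as
optional metadata.

Classification conventions worth stating explicitly:

* `assign_period()`: years before 2000 are `pre2000`; 2000–2020 are
  `post2000`; later years are retained in the database but excluded from
  current-window analyses (the current window is fixed).
* Presence means any class except `absent`; a record scored absent is never
  counted as presence anywhere.
* `present_unknown` counts as presence for the distribution index and is
  excluded from the abundance index — it informs occupancy, not abundance.
* Undefined indices (empty denominators) propagate as `NA`, never as 0,
  because 0 is a meaningful index value (all-absent, or all-rare).
* Broad regions are fixed: North = Canada + Washington, Central = Oregon +
  Northern California, South = Southern California + Mexico. Records
  labelled plain "California" are split at a configurable boundary latitude
  (default 34.4486°N, Point Conception) rather than a hard-coded rule.
* Records flagged sensitive keep their true coordinates for analysis; only
  exported copies have coordinates blanked (`redact_sensitive()`).
* Open-coast records (inside no estuary polygon and beyond the assignment
  tolerance) keep `estuary_id = NA`: they participate in network building
  but are excluded from per-estuary indices, since the estuary is the index
  replicate.
* Duplicate visits to a site within a period are counted as separate
  records, matching the index definitions, which are ratios of records.

## Statistical machinery

**Wilcoxon signed-rank.** The index data are saturated with ties and exact
zeros (many estuaries sit at index 0 or 1), so the test is implemented with
Wilcoxon's original zero-dropping convention and mid-ranks, and the exact
null distribution of the positive-rank sum is computed by a
generating-function convolution over the rank multiset. This stays exact
*under ties* (doubling mid-ranks makes them integers), which the usual
`psignrank`-based exact path cannot do. The exact path is used up to n = 25
non-zero differences — comfortably covering the replicate counts that arise
with the three-record filter — and a normal approximation with tie and
continuity corrections beyond that. Two-sided p-values sum the probability
of all statistic values at least as far from the null mean as observed,
which reduces to the familiar doubled tail for the symmetric null.

**Kendall correlation.** Tau-b (tie-adjusted), computed by direct
concordant/discordant pair counting. With up to 8 pairs the p-value is the
exact permutation tail over all n! orderings; beyond that the tie-corrected
normal approximation for the S statistic is used. Tau is undefined (and
flagged) when either margin has zero variance.

**Kruskal–Wallis, chi-square, Fisher.** These are standard steps and
delegate to `stats::kruskal.test`, `stats::chisq.test` (no continuity
correction; counts, not percentages, as input), and `stats::fisher.test`
(exact up to a grand total of 200; a seeded Monte Carlo estimate with its
standard error beyond). The fully tied Kruskal–Wallis case, where the tie
correction degenerates, is defined as H = 0.

**Selection intervals.** The simultaneous 95% intervals on use proportions
are Bonferroni-adjusted normal-approximation intervals ($z$ at
$\alpha/2k$ for $k = 6$ classes), the convention of the selection-ratio
literature the preference/avoidance rule comes from; Wilson score intervals
with the same adjustment are available by flag. The calls follow the
availability rule exactly: preference iff $p_i$ falls below the interval,
avoidance iff above, proportional otherwise. $w_i$ is defined as 0 when use
is zero and left undefined (flagged) when availability is zero with
non-zero use — an infinite ratio would be meaningless. The identity
$\sum_i w_i p_i = 1$ holds whenever every used class has non-zero
availability, and is asserted in the tests.

## Along-water distances and networks

The coastline is burned onto a regular grid: a cell is water iff its center
lies in no land polygon. Shortest paths run through water cells with
orthogonal steps costing one cell, diagonal steps $\sqrt2$ cells, and — at
the default 16-connectivity — knight moves costing $\sqrt5$ cells. A knight
move is allowed only if both cells flanking its chord are water, so paths
cannot jump across a thin land spit; diagonal steps may cut a land corner,
matching the behaviour of straight-line distance-accumulation tools. On
open water this discretization overestimates true Euclidean distance by at
most about 2.8% (16-connectivity) or 8.2% (8-connectivity); the package
documents and tests this distortion rather than pretending the raster
metric is exact. Distances are computed by a multi-source Dijkstra in C++
and truncated at the dispersal limit where one applies.

Network construction: presence records from 2000–2020 are snapped to the
nearest water cell (up to 1 km — records farther off the raster are
excluded with a warning, mirroring how low-accuracy records are treated),
linked when their along-water distance is at most `d_link`, and grouped by
connected components. Defaults follow the dispersal-network definition
anchored in the larval-dispersal literature: `d_link = d_max = 30` km. The
source material supports two linkage readings — 30 km point-to-point, or
overlapping 30-km buffers (which implies 60 km point-to-point) — so
`d_link` is configurable up to `2 * d_max` to emulate the buffer-overlap
reading, with the 30-km biological definition as the default. Likewise
`min_members` defaults to 2 (only singletons are excluded from networks)
and is configurable to 3 for the stricter three-point reading.

Network polygons are the union of members' `d_max` reachable zones,
vectorized as cell-boundary rings without smoothing so that polygon area
reproduces the mask cell count bit-for-bit. Adult networks clip those
zones to estuary polygons by cell-center membership. Inter-network
connectivity is an untruncated multi-source shortest path between polygon
cells; isolation is the mean of the distances to the nearest network north
and south by centroid northing (a deliberately simple, testable reading of
"north"), falling back to the single defined side for the endpoint networks and
undefined for a species with one network.

## The synthetic generator

Every pipeline stage is validated on synthetic coastlines and records with
known ground truth; no external data are downloaded. Scenarios are minimal
planar geometries — an open strip, a peninsula (spit) forcing a planted
along-water detour, an archipelago with three widely separated record
clusters, and an estuary chain — not realistic coastlines: they exercise
the algorithms (barrier detours, component recovery, estuary clipping), and
passing them demonstrates algorithmic correctness, not fidelity to real
coastline fractality, currents, or survey bias.

Defaults encode the study conditions the package is validated against,
chosen once: 20 estuaries; 12 records per estuary × species × period
(a realistic mid-size estuary record count under the three-record filter);
native presence probability $\theta = 0.8$ pre-2000 with an additive change
$\delta = -0.3$ after 2000, non-native $\theta = 0.3$ with $\delta = +0.3$
(the opposing temporal trends of the two species); common-given-abundance
fraction $\phi = 0.6$ / 0.5; 10% of presence records entered as
present-with-unknown-abundance; a ±0.1 uniform per-estuary jitter on
$\theta$ for estuary heterogeneity (set to 0 to plant exact values in
calibration tests); and regional substrate mixtures grading from soft
natural substrates in the north to riprap and other anthropogenic structure
in the south. Scenario extents are 100–300 km with 250–500 m cells: this
preserves the 30-km linkage geometry while keeping grids at desk scale;
the 10-m production cell size of a real coast-wide analysis is a
configuration choice, not a different algorithm. Generation is one seeded
random stream per scenario, making record sets a deterministic, bytewise
reproducible function of the configuration (a simpler design than derived
per-estuary sub-streams; partial regeneration is not a package feature).

```{r example}
cfg <- scenario_config(seed = 42, scenario = "open_strip", cell_size = 500)
sim <- simulate_records(cfg)
native <- filter(sim$records, species == "O_lurida")
ch <- paired_change(
  indices_by_estuary(native, "distribution", "pre2000"),
  indices_by_estuary(native, "distribution", "post2000"))
glance(ch)
```

## Numerical choices and degenerate inputs

* Grid indexing is column-major with row 1 at the southern edge; records
  snap to cell centers, so two records in one cell are the same node.
* Distance truncation marks cells beyond `d_max` unreachable rather than
  clamping, so reachable-zone areas are well-defined.
* Empty index denominators yield `NA` with the record count reported;
  `paired_change()` with fewer than two paired estuaries reports undefined
  statistics but still reports change percentages.
* Change percentages are rounded to integer percent, matching the usual
  reporting style for these analyses.
* Wilcoxon exact ties are handled by rank doubling; two-sided exact
  p-values use the symmetric-tail definition.
* `fisher_exact()` Monte Carlo runs under an explicit seed and reports its
  standard error.
* Estuary polygons that overlap produce an ambiguity warning and
  first-match assignment; estuary assignment within `max_assign_m` of a
  polygon uses true point-to-polygon distance, brute force over all
  estuaries.
* The tests that compare against 99% binomial recovery intervals use a
  joint criterion (at most one of 16 simultaneous intervals may miss),
  because asserting 16 marginal 99% intervals at once would reject a
  correctly calibrated generator about 15% of the time.

## Problem sizes used in validation

The validation suite runs entirely on synthetic data at desk scale: 50
random barrier grids of 40 × 40 cells checked cell-exactly against an
independent igraph shortest-path oracle; a 300 × 300 open-water grid for
the metric-distortion bound; 20 seeds × 2 barrier scenarios for exact
planted-network recovery; 200 randomized rank-test cases at n ≤ 8 against
exhaustive enumeration; 4 estuaries × 500 records per period for parameter
recovery; and 50 seeds of the 20-estuary decline scenario for detection
power. These sizes were chosen so the full suite completes in a few
minutes while still exercising every code path at meaningful scale.

## Known limitations

* No hydrodynamics: larval connectivity is a distance criterion, not a
  transport model (no currents, temperature, or salinity).
* The raster metric inherits up to ~3% distortion at 16-connectivity;
  reported distances are upper-bounded approximations of true along-water
  geodesics.
* Polygon holes are not supported in the GeoJSON reader; land masses are
  outer rings.
* Substrate availability profiles are inputs; the package does not derive
  them from shoreline map products, and no tidal-elevation stratification
  is attempted.
* The synthetic generator does not emulate observer bias, which in real
  crowd-sourced data (e.g. the strong skew of non-native records toward
  community-science sources) can dominate apparent patterns.
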