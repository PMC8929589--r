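# oysternet

Synthesizing intertidal oyster occurrence records into conservation-relevant
summaries: per-estuary **distribution and abundance indices** with
nonparametric tests of temporal change, **barrier-aware larval dispersal
networks** on a rasterized coastline, and **substrate use-versus-availability
selection analysis** with simultaneous confidence intervals.

The package targets spatial ecologists and conservation practitioners working
with site-level records of the native Olympia oyster (*Ostrea lurida*) and
the non-native Pacific oyster (*Magallana gigas*) on the North American
Pacific coast — or any comparable presence/abundance record compilation. A
record is a point at the center of a 20-m stretch of low intertidal
shoreline, scored common (>100 living oysters), rare (1–100), present with
unknown abundance, or absent.

## The statistics at the core

For a species in an estuary and period,

- **Distribution index** = presence records / (presence + absence records);
  0 means every record was an absence, 1 means no absences were recorded.
- **Abundance index** = common records / (common + rare records);
  merely-"present" records carry no abundance information and are excluded.

Temporal change (pre-2000 vs 2000–2020) is tested with a **paired Wilcoxon
signed-rank test** with each estuary as a replicate, keeping estuaries with
at least three records in both periods. The exact null is computed even
under ties via a rank-multiset convolution.

**Larval networks** are connected components of occupied sites linked when
their along-water distance (shortest path through water cells around
coastline barriers, multi-source Dijkstra) is ≤ 30 km; each network's
polygon is the union of its members' 30-km reachable zones, **adult
networks** are those polygons clipped to estuaries, and **isolation** is the
mean along-water distance to the nearest network north and south.

**Substrate selection** uses the selection index *w*ᵢ = *u*ᵢ/*p*ᵢ (use
proportion over availability proportion; >1 means used more than available)
with Bonferroni-adjusted simultaneous 95% CIs on *u*ᵢ: availability below
the interval ⇒ preference, above ⇒ avoidance, otherwise proportional use.

## Worked example

Everything below runs on synthetic data with known ground truth — no
downloads. Simulate a 20-estuary coastline where the native species declines
by 0.3 in presence probability after 2000, then test for the decline:

```r
library(oysternet)
library(dplyr)

cfg <- scenario_config(seed = 42, scenario = "open_strip", cell_size = 500)
sim <- simulate_records(cfg)

native <- filter(sim$records, species == "O_lurida")
ch <- paired_change(
  indices_by_estuary(native, "distribution", "pre2000"),
  indices_by_estuary(native, "distribution", "post2000"))
ch
#> Paired Wilcoxon change analysis (post2000 - pre2000)
#>   replicates (estuaries): 20
#>   V = 6, p = 2.4796e-05  [wilcoxon_signed_rank (exact)]
#>   declined 95%, increased 5%, unchanged 0%
```

All 20 estuaries had at least three records per period; the positive-rank
sum V = 6 and exact p ≈ 2.5 × 10⁻⁵ recover the planted decline, with 95% of
estuaries declining. `tidy(ch)` returns the per-estuary paired values,
`glance(ch)` the one-row summary, `autoplot(ch)` the paired-lines figure.

Dispersal networks on an archipelago scenario with three planted clusters:

```r
cfg <- scenario_config(seed = 42, scenario = "archipelago")
sim <- simulate_records(cfg)
snapped <- snap_to_water(sim$records, sim$grid, 1000)
net <- build_larval_networks(snapped, sim$grid, network_config())
select(net$networks, -mask, -polygon)
#> # A tibble: 3 × 6
#>   network_id species  n_members area_km2 centroid_x centroid_y
#> 1 O-1        O_lurida        12    3298.    169507.     40668.
#> 2 O-2        O_lurida        12    3329      99500.     40518.
#> 3 O-3        O_lurida        12    3338      30138.     39545.

edges <- optimal_connections(net$networks, sim$grid)
isolation_metric(net$networks, edges)
#> # A tibble: 3 × 4
#>   network_id dist_north_m dist_south_m isolation_m
#> 1 O-1                  NA         5000        5000
#> 2 O-2                5000         5000        5000
#> 3 O-3                5000           NA        5000
```

Each planted cluster is recovered as its own network (ids numbered north to
south), with ~3300 km² of reachable water each and 5-km along-water gaps
between neighboring network polygons.

Substrate selection against a uniform availability profile:

```r
use <- substrate_counts(filter(sim$records, species == "O_lurida"), "by_species")
sel <- selection_analysis(unlist(use[1, substrate_classes]),
                          availability_profile(setNames(rep(1/6, 6), substrate_classes)))
```

yields per-habitat *u*ᵢ, *w*ᵢ, the simultaneous CI, and a
preference/avoidance/proportional call (`autoplot(sel)` draws it).

`run_pipeline()` chains all stages — validation, estuary assignment,
summary, indices, change tests, networks, connectivity, substrate, selection
— writing CSV tables, GeoJSON layers, and a JSON run manifest; a thin CLI
wrapper lives at `inst/cli/oysternet.R` (`simulate` and `report`
subcommands).

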