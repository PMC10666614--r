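# sfer

Spill Footprint Exposure Risk (SFER) modelling for overland sewage spills.

Sanitary sewer overflows release untreated sewage onto land, where it flows
downhill, pools, and puts nearby residents at risk of pathogen exposure.
`sfer` models the exposed surface for each recorded spill from nothing more
than a digital elevation model (DEM) and a spill catalog (origin point +
volume), then aggregates footprints into zone-level risk metrics that
planners can map and rank.

## The model

Each spill gets a **three-part footprint**:

1. **Start accumulation zone** — terrain around the spill origin that lies
   *below* the origin's elevation, where sewage can pool. The search radius
   scales with spill volume (Eq. 1 below); grid cells are converted to
   4.5 m discs and wrapped in a concave hull, clipped to the volume-scaled
   "potential zone" disc.
2. **Flowpath corridor** — the D8 steepest-descent traceline from the
   origin across the (unfilled) DEM down to the first pit — the first cell
   with no lower neighbour, i.e. the first point of pooling — buffered to a
   15 m half-width worst-case path.
3. **End accumulation zone** — the same pooling construction around the
   traceline's end point.

The volume-to-radius rule is log-proportional with a 50 m cap:

```
s_i = log(q_i) / ( log(max Q) / 50 )        # metres; q in litres
```

clamped below by one DEM cell size so every zone covers at least one cell.
The ratio of logs makes the rule independent of the logarithm base, but not
of the volume units — quantities are litres throughout (a gallons flag is
available at CSV import).

Footprints aggregate into two zone metrics:

- **pRisk** (census-tract level): persons inside the tract's unioned
  footprints over the tract's resident population. Population comes from a
  LandScan-style count raster converted to 35 m discs; a disc that touches
  the footprints contributes its full count. Footprints are unioned first
  so repeated spills at one location are not double-counted
  (`mode = "chronic_sum"` keeps the multiplicity instead).
- **lRisk** (subwatershed level): fraction of the subwatershed's area
  covered by the unioned footprints.

Both are classified into quantile map classes (default quintiles), and
`prioritize()` intersects top-class tracts with top-class subwatersheds to
shortlist remediation sites.

The model is deliberately simple: no depression filling, no flow velocity,
infiltration, or dose–response — it is a screening tool that turns public
spill records into comparable, mappable exposure surfaces.

## Worked example

Everything below is reproducible — the synthetic generators are
deterministic given a seed, and this output is pasted from a real session.

```r
library(sfer)

# A smoothed random terrain, 400 m x 400 m at 10 m resolution
dem <- make_dem("random_smooth", n_rows = 40, n_cols = 40,
                cell_size = 10, seed = 42)

# 15 spill drafts: two duplicate-location pairs and a 20% invalid tail
spills <- make_spills(dem, n = 15, duplicate_pairs = 2,
                      invalid_fraction = 0.2, seed = 42)

fps <- build_footprints(spills, dem)
attr(fps, "validation")
#> # A tibble: 4 × 2
#>   reason      count
#>   <chr>       <int>
#> 1 kept           12
#> 2 coordinates     1
#> 3 flagged         1
#> 4 quantity        1

tidy(fps)
#> # A tibble: 12 × 10
#>   spill_id     x     y quantity buffer_size_m end_x end_y termination_reason
#>   <chr>    <dbl> <dbl>    <dbl>         <dbl> <dbl> <dbl> <chr>
#> 1 s001       145   395    266.           30.6    85   395 pit
#> 2 s002       145   395    480.           33.8    85   395 pit
#> 3 s003       295   235   5153.           46.8   335   275 pit
#> 4 s004       295   235     26.1          17.9   335   275 pit
#> 5 s005       315   285   9261.           50     335   275 pit
#> # ℹ 7 more rows

glance(fps)
#> # A tibble: 1 × 9
#>   n_footprints total_quantity_l q_max_l total_area_m2 union_area_m2
#>          <int>            <dbl>   <dbl>         <dbl>         <dbl>
#> 1           12           31275.   9261.        52372.        38881.
```

Note the union semantics at work: s001/s002 and s003/s004 are
duplicate-location pairs, so the union area (38,881 m²) is well below the
sum of the parts (52,372 m²). The sizing rule is easy to check by hand:

```r
buffer_size(c(10, 100, 1000, 10000), q_max = 10000)
#> [1] 12.5 25.0 37.5 50.0
```

Risk aggregation over a 2×2 zone tiling with a constant 3-person 90 m
population grid (tract populations are summed from the contained cells, so
numerator and denominator share a source):

```r
pop    <- make_population(dem, cell_size = 90, count = 3)
tracts <- make_zones(dem, 2, 2, "tract", pop = pop)
sws    <- make_zones(dem, 2, 2, "subwatershed")

p_rows <- classify_quantiles(population_risk(fps, tracts, pop), k = 5)
l_rows <- classify_quantiles(land_risk(fps, sws), k = 5)
l_rows[c("zone_id", "metric", "value", "exposed_area", "n_spills",
         "quantile_class")]
#> # A tibble: 4 × 6
#>   zone_id metric value exposed_area n_spills quantile_class
#>   <chr>   <chr>  <dbl>        <dbl>    <int>          <int>
#> 1 su_r1c1 lRisk  0.158        6339.        4              3
#> 2 su_r1c2 lRisk  0.436       17447.        5              5
#> 3 su_r2c1 lRisk  0.228        9113.        3              4
#> 4 su_r2c2 lRisk  0.109        4372.        3              2

prioritize(p_rows, l_rows, tracts, sws)
#> # A tibble: 1 × 5
#>   tract_id subwatershed_id geometry   point_x point_y
#>   <chr>    <chr>           <list>       <dbl>   <dbl>
#> 1 tr_r1c2  su_r1c2         <sfer_gem>     300     300
```

The north-east quadrant hosts the most footprint area and the top
population-risk tract, so it becomes the single priority site.
`plot_footprints(fps, dem)` and `plot_risk_map(sws, l_rows)` draw the
corresponding maps (ggplot2).

## Command line

An end-to-end pipeline ships in `exec/sfer`:

```sh
SFER=$(Rscript -e 'cat(file.path(find.package("sfer"), "exec", "sfer"))')
Rscript $SFER synth     --out demo/in --seed 3 --spills 12
Rscript $SFER footprint --dem demo/in/dem.asc --spills demo/in/spills.csv --out demo/fp
Rscript $SFER risk      --footprints demo/fp/footprints.geojson \
                        --tracts demo/in/tracts.geojson \
                        --subwatersheds demo/in/subwatersheds.geojson \
                        --population demo/in/population.asc --out demo/risk
Rscript $SFER tabulate  --spills demo/in/spills.csv
```

Every run writes `run_report.json` and `config_used.yml` for provenance;
re-running the same configuration produces byte-identical outputs.

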