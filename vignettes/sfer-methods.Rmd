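---
title: "SFER: model, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SFER: model, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfer)
```

## 1. What the model does

Overland sewage spills (sanitary sewer overflows) are point events: a
manhole, pipe, or pump station releases a known volume at a known location,
and the sewage then moves and pools under gravity. The SFER (Spill
Footprint Exposure Risk) model turns each record into a polygon — the
*footprint* — of land plausibly touched by the spill, using only a DEM and
the record itself, and then aggregates footprints into two zone-level risk
ratios. It is a screening model: it trades hydraulic fidelity for the
ability to process thousands of records from public spill registries with
no site-specific data.

### 1.1 Footprint construction

A footprint has three parts (built by `build_footprint()`):

**Volume-scaled sizing.** The radius of each accumulation zone comes from
the spill volume $q_i$ (litres) relative to the largest volume in the
catalog, $\max Q$:

$$ s_i \;=\; \frac{\log q_i}{\log(\max Q)\,/\,50\,\mathrm{m}} $$

so the biggest spill gets the 50 m cap and a spill with half the
log-volume gets 25 m. The ratio of logarithms makes the rule base-invariant
but *not* unit-invariant, which is why the package fixes quantities to
litres (`read_spills(gallons = TRUE)` converts at 3.78541 L/gal). The raw
formula is non-positive for $q \le 1$, so it is clamped below by
`min_buffer_m`, defaulting to one DEM cell size — a zone should never be
smaller than the datum that produced it. See `buffer_size()` and
`sizing_config()`.

**Accumulation zones.** Around the start point (and later the traceline
end point) a *potential zone* disc of radius $s_i$ is drawn. Every
non-nodata DEM cell becomes a point with a 4.5 m disc (`grid_points()`);
discs whose elevation is **strictly below** the centre's elevation and
that reach the potential zone are collected, together with the centre's
own disc, and wrapped in a concave hull which is clipped back to the
potential zone (`accumulation_zone()`). Strict inequality means a flat
neighbourhood contributes nothing — pooling needs a drop. The centre's own
disc guarantees a non-empty zone even when every neighbour is higher.

The 4.5 m point discs deliberately over-cover a cell (π·4.5² ≈ 63.6 m²
against a 25 m² cell at 5 m resolution): gaps between selected cells would
otherwise fragment the hull and underestimate the pooling area.

**Traceline and corridor.** Flow routing is D8 on the *unfilled* DEM: each
cell drains to whichever of its eight neighbours has the steepest
distance-weighted drop (diagonals divided by √2), computed by
`flow_direction()`. A cell with no strictly lower neighbour is a **pit** —
the first point of pooling — and that is exactly where a trace should stop,
which is why no depression filling is applied. `trace_flowpath()` follows
the codes from the spill origin until a pit, the grid edge, or a nodata
cell, recording which (`termination_reason`). The polyline is buffered to a
15 m half-width with round caps and joins (`geom_buffer_path()`),
representing a worst-case overland path rather than a hydraulically
modelled one. The three polygons are unioned into the footprint.

Two properties follow from the construction and are enforced by tests:
traces descend strictly (so they terminate within `n_rows × n_cols` steps),
and footprints at the same location share an identical traceline whatever
the volume — only the zone radii change.

### 1.2 Risk metrics

For a census tract $ct$ with resident population and a set of footprints
$A_1,\dots,A_n$:

$$ \mathrm{pRisk}(ct) \;=\;
   \frac{\sum_{\ell \in L}\; \mathrm{count}(\ell)\,
         \big[\,\mathrm{disc}(\ell) \cap
               \big(\textstyle\bigcup_i A_i \cap ct\big) \ne \emptyset\,\big]}
        {\mathrm{population}(ct)} $$

where $L$ is a LandScan-style grid of person counts converted to 35 m
discs (`population_cells()`, `read_population()`). A disc that touches the
clipped footprint union contributes its **full** count — no areal
weighting. Because the numerator comes from ambient gridded counts and the
denominator from the census, pRisk can exceed 1; `population_risk()`
reports such values with a warning rather than clamping, and flags the
undefined 0-population/positive-exposure case.

For a subwatershed $sw$:

$$ \mathrm{lRisk}(sw) \;=\;
   \frac{\mathrm{area}\big(\bigcup_i A_i \,\cap\, sw\big)}
        {\mathrm{area}(sw)} \;\in\; [0, 1]. $$

The union is the default because repeat spills at one outfall must not be
double-counted; `mode = "chronic_sum"` keeps the multiplicity instead,
which weights chronically spilling locations and can push the ratios above
the union values (never below — a tested invariant).

Rows are classified into $k$ quantile classes (default 5) by
`classify_quantiles()`, which is rank-based: `ceiling(k·rank/n)` with ties
sharing the lower class. Heavy ties collapse the classes; that is reported,
not fatal, and `prioritize()` — the intersection of top-class tracts with
top-class subwatersheds — uses the top *occupied* class so a collapsed
classification still yields a shortlist. `zonal_mean()` supports overlays
such as mean imperviousness over the top subwatersheds, and
`tabulate_causes()` reproduces cause-breakdown tables with half-up rounding
to two decimals.

## 2. Parameter defaults

| Parameter | Default | Meaning |
|---|---|---|
| `max_buffer_m` | 50 | accumulation-zone radius at `q = max(Q)` |
| `min_buffer_m` | one cell size | clamp floor for the sizing formula |
| `traceline_buffer_m` | 15 | corridor half-width |
| `point_buffer_m` | 4.5 | elevation-point disc radius |
| `concavity` | 0.8 | hull tightness in (0, 1]; 1 = convex hull |
| `pop_buffer` | 35 | population-cell disc radius |
| `edge_policy` | `stop_at_edge` | border cells with no downslope neighbour pool (`flow_outward` routes them off-grid instead) |
| `k` | 5 | quantile classes (quintiles) |

The defaults are the model's study conditions, not tuning knobs: the tests
run against them. The edge policy is exposed because GIS D8 tools differ on
edge handling and neither convention is obviously right; both are tested
and only border cells differ between them.

## 3. Synthetic generators

Nothing in the package needs a download: `make_dem()`, `make_spills()`,
`make_population()` and `make_zones()` emulate the four real inputs.

- **Terrains** have known analytic structure. `plane` gives closed-form
  traces (straight lines of known length) and corridor areas
  ($L \times 30\,\mathrm{m} + \pi\,15^2$); `basin` (Gaussian depression)
  has a unique pit at the centre; `ridge_valley` funnels flow into a
  valley line; `random_smooth` (seeded noise + 3×3 mean smoothing) supplies
  realistic irregular relief. The default 10 m cell matches the honest
  scale of 1/3 arc-second elevation tiles.
- **Spill catalogs** draw log-uniform volumes in 10–10,000 L — spill
  registries span orders of magnitude, which is also why Eq. 1 is
  logarithmic. Optional duplicate-location pairs exercise union semantics
  and an invalid fraction exercises validation, cycling the three real
  failure modes (bad geocode, unusable quantity, flagged record).
- **Population and zones**: constant-count 90 m grids give closed-form
  exposure expectations; rectangular tilings give closed-form areas, and
  tract populations can be summed from contained cells so the pRisk
  numerator and denominator share a source.

All generators take explicit seeds, restore the caller's RNG state, and
are byte-reproducible (`with_local_seed`); footprint construction itself
draws no random numbers.

## 4. Numerical choices

- **Geometry engine.** Boolean overlays and buffering use the Clipper
  library (polyclip), which snaps coordinates to an integer grid of about
  range/2³¹ — roughly nanometre precision on metre-scale scenes. Areas of
  analytically equal shapes therefore agree to ~1e-9 relative, which is the
  noise floor the tests assert against (at 1e-6).
- **Even-odd ring sets.** A geometry is a list of rings under the even-odd
  rule; holes are rings at odd nesting depth. Areas and centroids weight
  rings by nesting-depth parity (point-in-polygon count) rather than by
  orientation, so hand-built or round-tripped geometries measure correctly
  whatever their winding.
- **Concave hull.** The chi-shape algorithm: Delaunay-triangulate the
  disc-vertex cloud, then repeatedly shave boundary triangles whose
  boundary edge exceeds
  $\lambda = l_{\min} + \mathrm{concavity}\,(l_{\max} - l_{\min})$,
  refusing removals that would pinch the boundary (the opposite vertex
  must not already lie on it). `concavity = 1` removes nothing and equals
  the convex hull exactly. Triangle faces are extracted from the deldir
  edge list by common-neighbour enumeration with an Euler face-count
  shortcut; co-circular clouds (regular disc vertices) are the common case
  and are handled deterministically.
- **D8 details.** Ties for steepest drop break to the first direction
  clockwise from east; flats are pits; nodata cells neither give nor
  receive flow. An exhaustive per-cell neighbour-scan oracle checks the
  vectorised implementation cell-for-cell across random grids.
- **Tabulation rounding** is half-up (`floor(x·10² + 0.5)/10²`) because
  banker's rounding (R's `round`) would disagree with published
  two-decimal tables at exact half-cents.
- **Formats.** Rasters: ESRI ASCII grid. Vectors: GeoJSON (MultiPolygon,
  one ring per polygon, even-odd preserved; the projected CRS label rides
  in a top-level `crs_label` member since GeoJSON proper mandates
  WGS84-degree coordinates, which this model cannot use — metre units are
  load-bearing everywhere). Text round-trips preserve coordinates to
  ~1e-13 relative. Mixed-CRS inputs and geographic CRS labels are rejected
  before any computation.

## 5. Limitations

- **No hydraulics.** No volume conservation, infiltration, roughness, or
  velocity: the corridor width and zone radii are calibrated conventions,
  not physics. Footprint *area* is not spill *extent*.
- **D8 is single-direction.** Divergent flow over convex terrain is
  funnelled into one cell line; D-infinity or multiple-flow-direction
  routing would widen corridors but is out of scope.
- **Unfilled DEM sensitivity.** Pits include real depressions *and* DEM
  noise; a noisy DEM fragments tracelines early. That is by design (first
  pooling point) but makes results resolution-dependent.
- **Geocode accuracy dominates.** The whole footprint hangs off the origin
  coordinate; registry geocoding error translates directly into footprint
  error. Validation can only drop records that are visibly unusable.
- **Full-count disc intersection** overstates exposure at footprint edges
  (a 1-person sliver contact counts the whole 35 m cell) and pRisk mixes
  ambient counts with census denominators, so values above 1 occur and
  are flagged rather than hidden.
- **Quantile classes are relative.** A top-quintile tract in a low-spill
  region can carry less absolute risk than a mid-quintile tract elsewhere;
  the classes support mapping and ranking within a study area only.
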