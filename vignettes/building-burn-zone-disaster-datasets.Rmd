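---
title: "Building wildfire burn-zone disaster datasets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building wildfire burn-zone disaster datasets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burnzones)
```

## The problem

Wildfires become *disasters* when their burn zones reach communities: people
die, structures burn, and governments declare emergencies. No single U.S.
agency records all of this. Incident status reports (ICS-209 style) carry
fatality and structure counts nationally; California's annual large-fire
report tables carry cleaner, disaggregated counts for one state; federal
fire-assistance declarations (FMAG style) mark events that exhausted local
capacity; and burn perimeters live in entirely separate remote-sensing and
interagency products. `burnzones` implements a reproducible pipeline that
harmonizes such sources into a single spatial dataset of burn-zone disasters,
and ships a synthetic-data generator that emulates every source schema so the
whole pipeline can be exercised and validated offline.

A fire qualifies as a **burn-zone disaster** when it meets at least one harm
criterion — ≥1 civilian fatality, ≥1 destroyed structure, or a federal
fire-assistance declaration — *and* burned in or near a community, defined as
either a smoothed population density of ≥96 people/km² within a
size-dependent buffer, or overlap with wildland-urban interface (WUI)
intermix/interface land.

## Pipeline stages and their rules

1. **Standardize.** Names are uppercased, stripped of punctuation and
   USPS-abbreviated token-by-token ("MOUNTAIN" → "MTN"; whole tokens only, so
   "MOUNTAINEER" survives). County names resolve against a gazetteer with an
   alias rule for heavily abbreviated counties ("LA" → "LOS ANGELES").
   Records ignited before 2000 and non-fire rows (e.g. COVID-19 declarations
   that leak into incident databases) are dropped into a reasoned rejection
   log; cleaning is idempotent and conserves rows.

2. **Link.** Two records describe the same fire when their state–county sets
   overlap, ignition dates differ by ≤30 days, and some pair of their names
   has Jaro-Winkler distance ≤0.25 (prefix factor 0.1). Fires are the
   connected components of this match graph, so A–B and B–C links merge all
   three. Conflicts resolve by precedence: the state annual-report source
   wins counts and dates when present; otherwise counts take the maximum
   across sources, ignition the earliest date and containment the latest.
   Within one source, rows with distinct ids inside a cluster are complex
   member fires; their counts are summed (configurable to max).

3. **Criteria.** Era-dependent fallbacks mirror the sources' reporting
   history: civilian fatalities were not broken out in 2000–2013, so any
   fatality qualifies there; damaged and destroyed structures were combined
   in 2007–2009, so ≥1 combined count qualifies then. Eras key on ignition
   year (the sources report by incident year; a record with no usable year is
   evaluated strictly and annotated).

4. **Geolink.** Geometry attaches by tiers, first success wins: shared
   interagency id; MTBS-flavor by name + county-within-10-km + date ±30 d;
   FIRED-flavor by origin-in-perimeter + date (that product has no names);
   NIFC-flavor by name + location + ignition year ±30 d; then a circular
   buffer whose planar area equals the reported burn area; then a bare point;
   then county-only with no geometry. Fires linked to one perimeter merge
   (max counts, min ignition, max containment, FMAG if any).

5. **Community.** Population-per-cell grids (100-m cells, 5-year epochs)
   become density layers (people/km²) smoothed by an unweighted focal mean
   over all cells whose centres lie within 300 m — 29 cells on the 100-m
   lattice. Fires <1,000 acres (or point-only) get 10-km buffers, ≥1,000
   acres get 20-km buffers; the density flag is max smoothed density ≥96.
   WUI overlap is evaluated on the *unbuffered* burn geometry. The community
   flag is the OR of the two.

6. **Report.** GeoJSON output (lon/lat, null geometry for county-only
   records), a generated data dictionary, count tables, percent shares
   (half-up to one decimal) and a Mann-Kendall trend test with tie-corrected
   variance and continuity correction.

## The synthetic world

The generator states a world rather than exposing dials to tune: a 120 × 120
km equal-area extent split into two states and a 4 × 4 county grid; 12 towns
as isotropic Gaussian population kernels (any unimodal kernel satisfies the
contracts); vegetation high in wildland and suppressed where housing is
dense; 100-m grids; fires with lognormal burn areas (median 600 acres),
ignitions uniform over 2000–2025, ~10% of fires killing a civilian, ~35%
destroying structures, 12% receiving declarations, 15% of fires grouped into
co-located complexes. Sources render with era-dependent missingness, source-
specific identifier availability (shared ids on ~50% of fires; the FIRED
flavor nameless; the NIFC flavor with year only), regional size cutoffs
(1,000/500 acres west/east for the MTBS flavor, 300 acres for the state
annual report), and bounded noise: at most one in-token character
substitution per name and ≤7 days of date jitter per source, both strictly
inside the linkage tolerances; counties are unperturbed by default.

Truth incident names are drawn so distinct incidents are mutually >0.3 apart
in Jaro-Winkler distance (one name per distinct leading word — the Winkler
prefix bonus makes names sharing a first word nearly indistinguishable).
Real incident names are administratively distinct in the same way; this
keeps ground truth unambiguous for recovery tests. Worlds larger than the
vocabulary (~220 leading words) fill with unique but less-separated pairs,
which only weakens ground-truth-purity tests, not pipeline correctness.

What a green test does **not** establish: the generator does not emulate
OCR damage, schema drift within a source, county boundary changes, geocoding
errors, or the true spatial autocorrelation of wildfire occurrence. Recovery
results on synthetic worlds bound pipeline logic errors, not real-world
match rates.

## Numerical and design choices

- **Thresholds as stated**: 96 people/km² (250/mi² truncated), 6.17
  houses/km² (1 per 40 acres, truncated to 2 dp), 0.25 Jaro-Winkler with 0.1
  prefix factor, 30-day windows, 10/20-km buffers at the 1,000-acre cutoff
  (≥ is large), 300-m smoothing radius, 2.4-km interface distance to a ≥5
  km² patch with ≥75% vegetation.
- **Jaro-Winkler variant**: prefix capped at 4, no boost threshold —
  the common default of the string-distance routines used for this kind of
  record linkage; validated against an independently written oracle and
  hand-derived values.
- **Smoothing weights**: the density smoother uses uniform weights over
  cells whose centres fall within the radius. The weighting scheme is
  pluggable in principle; uniform is the only one shipped because no other
  is specified anywhere upstream.
- **All geometry is planar.** The package implements shoelace areas,
  ray-casting containment, point-to-polygon distances and Minkowski buffers
  in an equal-area km frame (an Albers-style working frame); lon/lat appears
  only at I/O. Buffered-zone membership uses exact distance-to-geometry,
  which equals Minkowski-buffer containment for any simple polygon; explicit
  buffer rings (for export) use convex-hull offsetting and are conservative
  for concave shapes.
- **Interface patches** use 8-connectivity; connectivity is unstated
  upstream and 8 is the more inclusive convention.
- **Missing dates in matching**: records with no ignition date fall back to
  the declaration date; if still dateless, the date condition is waived by
  default (configurable) so county + name evidence can still link.
- **Epoch choice**: ignition year rounds half-up to the nearest 5-year
  population epoch.
- **Percent rounding is half-up** to one decimal. Two shares printed in the
  source literature (5.2% for 327/6,212 and 9.6% for 593/6,212) are
  inconsistent with any standard rounding of their printed counts; the
  package reports recomputed values and the audit notes such discrepancies
  rather than matching them.
- **Exact Mann-Kendall p-values** (inversion-count recursion) are available
  for tie-free series of n ≤ 10; the default is the normal approximation
  with continuity correction, which is what the trend statistics in this
  literature use.
- **County-only records** cannot be buffered; they keep `community_flag =
  NA`, stay in the full output, and are excluded from the flagged disaster
  subset.
- **Caching**: `run_pipeline()` can cache the simulated world keyed by an
  md5 of the configuration, so reruns with an unchanged config skip
  simulation.

## Degenerate inputs and tie-breaks

Empty name strings compare at distance 0 only to other empty strings (both-
empty convention, documented in `jw_distance()`). Equal resolved dates break
ties by source order (redbooks, ics209, fmag) via deterministic record
ordering. Perimeter candidates tie-break by name distance, then date gap,
then perimeter id. Zero-area or two-vertex rings are repaired away before
matching; fires with neither origin nor county are rejected with a reason.

## Known limitations

- The working frame is a local cylindrical equal-area approximation anchored
  at the extent centre; over continental extents a true Albers projection
  would be required.
- Explicit buffer rings around strongly concave perimeters are convex-hull
  based and therefore over-cover; all decision-making paths avoid them.
- The pipeline does not model monetary-loss or evacuation-based criteria
  (descriptive variables only) and does not re-derive perimeters from
  imagery.
- Headline counts from the real multi-agency record (6,212 disasters,
  τ = 0.997, state rankings) are not reproducible from synthetic worlds and
  are not asserted anywhere; the acceptance suite checks arithmetic
  identities, recovery properties, and audit invariants instead.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(world = world_config(n_fires = 200), seed = 7,
                       out_dir = "out")
res <- run_pipeline(cfg)
res$stages
res$summaries$by_criterion
mann_kendall(res$summaries$by_year$n)
```

The audit (written to `out/audit.md`) re-derives the disaster flag from the
stored criteria and community fields, checks that rendered rows equal cleaned
plus rejected rows, and reports the share of criterion-meeting fires that
qualified as disasters.
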