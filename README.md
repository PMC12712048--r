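# burnzones

Construction of wildfire burn-zone disaster datasets from multi-source
incident records.

## What this is for

Researchers studying the health, economic and demographic consequences of
wildfires need to know *which* fires actually reached communities — not just
where fires burned. That information is scattered: national incident status
reports (ICS-209 style) hold fatality and structure counts; state annual
large-fire reports hold cleaner counts for one state; federal
fire-assistance declarations (FMAG style) mark events that overwhelmed local
response; burn perimeters live in separate remote-sensing products (MTBS-,
FIRED-, NIFC-style) with incompatible identifiers. `burnzones` harmonizes
these flavors of sources into one spatial dataset of **wildfire burn-zone
disasters**: fires with

- ≥ 1 civilian fatality, **or** ≥ 1 destroyed structure, **or** a federal
  fire-assistance declaration, **and**
- a burn zone in or near a community — maximum smoothed population density
  ≥ 96 people/km² within a 10-km buffer (fires < 1,000 acres) or 20-km
  buffer (≥ 1,000 acres), or overlap with wildland-urban interface (WUI)
  intermix/interface land.

## Method at a glance

Records for the same fire are found by fuzzy linkage: state–county overlap,
ignition dates within 30 days, and Jaro-Winkler name distance

    d_JW(a, b) = 1 − [ J(a,b) + ℓ·p·(1 − J(a,b)) ] ≤ 0.25,   p = 0.1, ℓ ≤ 4

where `J` is the Jaro similarity. Clusters are connected components of the
match graph; conflicts resolve by source precedence (state annual report
wins, otherwise max counts / earliest ignition / latest containment). Harm
criteria use era-dependent fallbacks (any fatality in 2000–2013 when
civilian deaths were not broken out; combined damaged/destroyed counts in
2007–2009). Geometry attaches in tiers — shared interagency id, name +
county + date against perimeter sets, origin + date for the nameless flavor,
then a circular buffer with the reported area, a bare point, or county-only.
Community proximity uses a 300-m focal-mean density smoother (29 cells on
the 100-m lattice) and WUI overlap of the raw geometry. Trends are
summarized with the Mann-Kendall statistic (tie-corrected variance,
continuity correction).

A first-class synthetic-data module generates a seeded "fire world"
(counties, towns, vegetation/housing grids, ground-truth fires) and renders
it into every source flavor with era-faithful missingness and bounded noise,
so the full pipeline is testable offline with known truth.

## Worked example

```r
library(burnzones)
res <- run_pipeline(pipeline_config(world = world_config(n_fires = 500),
                                    seed = 42))
res$stages
#>                 stage   n
#> 1       rendered_rows 676
#> 2        cleaned_rows 672
#> 3       rejected_rows   4
#> 4     canonical_fires 437
#> 5         preliminary 233
#> 6 after_geolink_merge 233
#> 7           disasters 145
table(res$records$link_method)
#>         circular_buffer             county_only       fired_origin_date
#>                      16                       4                     101
#> mtbs_name_location_date nifc_name_location_year               shared_id
#>                      44                      27                      41
res$audit$ok
#> [1] TRUE
```

Reading: 676 rendered source rows cleaned to 672 (4 junk rows rejected with
reasons), linked into 437 canonical fires, of which 233 met a harm
criterion; all 233 received a geometry assignment (or county-only status),
and 145 also met the community criterion — those are the flagged disasters.
The audit re-derives every flag from stored fields and checks row
conservation at each stage.

Write the dataset and its data dictionary:

```r
write_outputs(res$records, "wildfire_disasters.geojson", res$world$frame)
```

CLI equivalent:

```sh
Rscript -e 'burnzones::burnzones_main()' run --seed 42 --out out_dir
```

## Layout

- `R/world.R` — synthetic fire world and source/perimeter rendering
- `R/standardize.R`, `R/jaro_winkler.R`, `R/linkage.R` — cleaning and fuzzy
  linkage
- `R/criteria.R`, `R/geolink.R`, `R/community.R` — harm criteria, tiered
  geometry, community proximity
- `R/report.R`, `R/pipeline.R`, `R/cli.R` — outputs, orchestration, CLI
- `R/geometry.R`, `R/grid.R`, `R/wui.R` — planar geometry, gridded layers,
  WUI classification
- `vignettes/building-burn-zone-disaster-datasets.Rmd` — methods and design
  rationale
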