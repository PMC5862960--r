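# sharkmove

Residency and home-range analysis for island-associated shark telemetry.

Large coastal sharks — tiger sharks around oceanic high islands are the
motivating case — are tracked with two complementary tag types: dorsal-fin
Argos satellite transmitters that yield error-graded positions whenever the
fin breaks the surface, and surgically implanted coded acoustic
transmitters logged by moored receivers whenever the animal passes within
detection range (up to ~900 m). `sharkmove` implements the analysis chain
that turns those two data streams into movement ecology results, for
researchers working with this kind of telemetry:

- **Argos track cleaning** — class-Z removal, automated distant-outlier
  removal, and the location-class anchored swim-speed filter: LC 1/2/3
  (and GPS-quality) fixes anchor the filter; a class 0/A/B fix is retained
  only inside a v<sub>max</sub> = 4.2 km/h great-circle buffer of its
  anchor and at sea. Temporal clusters are thinned to their best fix, and
  tracks are projected to UTM for planar work.
- **LoCoH home ranges** — local convex hulls under the k, r and adaptive-a
  neighbour rules (a-rule: nearest neighbours added while the sum of their
  distances to the root stays ≤ a), density-sorted isopleths (area and
  centroid by an exact polygon-union algorithm), the published a-selection
  rule (smallest a with a gap-free outer isopleth and ≤1% land overlap),
  and depth-thresholded exclusion of offshore loops beyond the 4,000 m
  isobath.
- **Bathymetry harvesting** — bilinear seafloor depth under surface fixes
  (never swimming depth), multi-resolution coastal/offshore grids, and
  per-sex depth-frequency profiles with between-shark standard errors.
- **Acoustic residency metrics** — monitoring windows (receiver deployment
  ∩ transmitter battery life ∩ analysis period, in local calendar days at
  UTC−10), visit segmentation (30-min gap or receiver change; single
  detections = 7.7 min by the duty-cycle convention), the Site Fidelity
  Index SFI = 100 × days detected / monitored days, detection-day
  frequency, co-detection summaries and per-shark summary tables.
- **Temporal patterns** — distinct sharks per pooled hourly/monthly bin
  and the two-sample Kolmogorov–Smirnov test against a uniform-at-mean
  null (D exact over tie-aware ECDFs; exact small-sample p for ≤ 12 bins).
- **Hurdle model assembly** — zero-inflated detection data split into
  presence/absence and proportional tables with log-listening-day offsets,
  centred/scaled predictors, Pearson/VIF collinearity screening, a
  declarative mixed-model specification (fits are delegated to standard
  engines such as lme4/mgcv), and AICc ranking with Akaike weights.
- **A synthetic study system** — island seascapes with realistic
  shelf/slope structure, core-attracted shark movement with land
  reflection and surfacing, duty-cycled acoustic transmission, and Argos
  fixes with class-dependent error generated only during 6–12 min/h
  satellite coverage. Everything is seeded and bit-reproducible, so the
  whole pipeline is testable without any telemetry download.

All user-facing functions take and return tibbles and chain with the
pipe; result objects have `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` ggplot2 graphics.

## Worked example

Simulate a core-attracted shark on a synthetic island, clean its Argos
track, and estimate its home range:

```r
library(sharkmove)

island <- tibble::tibble(name = "Moku", lat = 20.8, lon = -156.6,
                         land_radius_km = 15, shelf_width_km = 12)
grid <- generate_seascape(island, resolution = 0.01)

params <- movement_params(center_lat = 20.95, center_lon = -156.45,
                          attraction_per_h = 0.5, noise_km = 0.15)
track <- simulate_shark_track("S1", params, grid, duration_days = 60,
                              step_min = 5, seed = 11)

fixes <- simulate_argos_fixes(track, seed = 12)          # 129 fixes
filtered <- filter_argos(fixes, reference = c(20.95, -156.45), grid = grid)
table(filtered$reason, useNA = "ifany")
#> cluster_thinned            land           speed            <NA>
#>              61               2               3              63

planar <- project_to_planar(argos_retained(filtered))    # 63 retained fixes
hulls <- locoh_hulls(planar, method = "a", value = 20000)
iso <- build_isopleths(hulls, levels = c(0.10, 0.25, 0.50, 0.95))
tidy(iso)
#> # A tibble: 4 × 6
#>   level area_km2 fraction_enclosed n_hulls centroid_x centroid_y
#>   <dbl>    <dbl>             <dbl>   <int>      <dbl>      <dbl>
#> 1  0.1      2.45             0.508       1    765204.   2318682.
#> 2  0.25     2.45             0.508       1    765204.   2318682.
#> 3  0.5      2.45             0.508       1    765204.   2318682.
#> 4  0.95    40.7              0.968      59    764465.   2320041.
```

The core isopleths collapse onto a single dense hull of 2.45 km² centred
within ~150 m of the programmed attraction point (UTM 765204 E,
2318682 N vs the centre's 765028 E, 2318743 N), while the 0.95 isopleth
spreads over 40.7 km² of shelf — the core-structured home range the
simulator programs and the estimator recovers. `autoplot(iso)` draws the
nested polygons over the fix cloud.

On the acoustic side, a shark programmed to visit a receiver with daily
probability 0.3 over 400 monitored days comes back with an SFI of 29.5%
(118 detection days / 400), i.e. one visit every ~3.4 days
(`sfi_equivalent_revisit_interval`).

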