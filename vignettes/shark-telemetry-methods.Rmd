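---
title: "Methods: residency and home-range analysis for island-associated shark telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residency and home-range analysis for island-associated shark telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sharkmove)
library(dplyr)
```

# The problem

Large coastal sharks around oceanic islands are monitored with two
complementary tag types: fin-mounted Argos satellite transmitters that
yield error-graded positions whenever the fin breaks the surface, and
surgically implanted coded acoustic transmitters logged by moored
receivers whenever the animal passes within detection range (up to about
900 m). `sharkmove` implements the full analysis chain for such data:
cleaning Argos tracks, estimating utilisation distributions with local
convex hulls, harvesting seafloor depth under surface fixes, converting
receiver logs into monitoring-window-adjusted residency metrics, testing
diel and seasonal patterns, and assembling hurdle-structured tables for
mixed-model analysis. Because real telemetry of this kind is rarely
deposited, the package ships a synthetic seascape/movement/telemetry
simulator with the same statistical structure, so every stage is testable
end to end.

# The synthetic study system

`generate_seascape()` builds islands the way oceanic high islands are
shaped: a land core, an insular shelf ramping from the shore down to a
shelf break at 200 m, and a steep slope descending to abyssal depth. The
default shelf-break depth (200 m) and the 100–200 m break zone match the
bathymetry of such islands; the abyssal floor (4,500 m) and slope width
(25 km) are round values in the realistic range and only matter for the
offshore-exclusion logic, which needs water deeper than 4,000 m to exist.

`simulate_shark_track()` is a biased correlated random walk: each step
pulls the animal a fraction `attraction_per_h * dt` of the way toward a
core location, adds isotropic Gaussian noise, truncates the step to the
maximum sustained speed (default 4.2 km/h, the empirical threshold used
by the speed filter), and redraws any step that would land ashore
(reflection, not absorption — sharks do not beach). At-surface flags are
drawn independently per step with probability 0.15, the middle of the
10–20% surface-time range reported for the species from depth-logging
tags. This walk produces the core-structured home ranges the LoCoH
analysis is designed to recover; it deliberately omits tides, currents,
temperature and memory effects, so passing tests demonstrate that the
machinery recovers programmed structure, not that real sharks behave like
the simulator.

`simulate_acoustic_detections()` emits pulse trains of uniform 3–5 s
duration separated by uniform 20–230 s silences, the coded-transmitter
duty cycle the visit conventions are built on; the closed-form mean cycle
is 129 s, about 27.9 detections per hour for an animal parked inside
detection range. Every deployed receiver within range logs each
transmission until the nominal battery life ends.

`simulate_argos_fixes()` generates fixes only while the animal is at the
surface during satellite coverage, drawn as one window of 6–12 minutes
per hour (the regional average). Surfaced minutes inside coverage yield a
fix with probability 0.25 — coverage minutes are stated by the tag
literature but per-pass fix yield is not, so this is a single documented
choice, not a tuned value. Location classes follow a configurable
distribution (default 3:0.10, 2:0.15, 1:0.15, 0:0.20, A:0.20, B:0.20, an
Argos-typical mix) with isotropic Gaussian error at the class RMS
(LC3 150 m, LC2 300 m, LC1 1,000 m; the unrated classes default to 3, 5
and 10 km). Class Z carries no usable position.

Reproducibility: every simulator takes one integer seed and derives a
separate named stream per component (movement, duty cycle, Argos
windows), so components can be varied independently while the whole run
stays bit-reproducible.

# Argos filtering

The filter pipeline keeps every fix in the table and flags removals with
a reason (`class_z`, `distant_outlier`, `speed`, `land`,
`cluster_thinned`), so provenance survives the whole analysis.

* **Class Z** fixes carry no usable position and are dropped outright.
* **Distant outliers**: manual removal of obviously spurious distant
  positions is automated as a radius rule around the tagging site. The
  default 2,500 km comfortably exceeds the longest genuine offshore
  excursion documented in the region (1,460 km), so real behaviour is
  never clipped.
* **Speed filter**: location classes 1/2/3 (and GPS-quality fixes, class
  G) anchor the filter and are never removed by it. A class 0/A/B fix is
  kept only if it lies within a 4.2 km/h buffer of the most recent
  anchor — great-circle distance over elapsed time — and at sea. The
  buffer is evaluated as a straight line; whether a path-around-land
  buffer was ever intended is unknowable from a rule statement alone, so
  the at-sea check covers the land side explicitly. Fixes before the
  first anchor are judged against the first subsequent anchor rather than
  discarded. Retained 0/A/B fixes never become anchors. The filter is
  idempotent.
* **Temporal thinning**: maximal runs of fixes whose successive gaps are
  all strictly below a threshold (default: the median inter-fix interval
  of the retained track) collapse to their best fix (highest location
  class, earliest on ties). The strict inequality means a run sampled at
  exactly the median interval is not a cluster; with a knife-edge input
  whose cluster gaps equal the overall median the rule therefore leaves
  the run alone, which we consider the defensible reading of a
  median-based re-sampling threshold.

Planar work uses an in-package transverse Mercator (UTM, default zone 4)
projection accurate to well under 1 m in zone; distances on the sphere
use the haversine with radius 6,371 km everywhere, so the km/h threshold
means the same thing in the simulator and the filter.

# Local convex hull home ranges

Three neighbour rules are provided: `k` (root plus k−1 nearest), `r`
(all points within a fixed radius) and the adaptive `a` rule (nearest
neighbours added while their summed distances to the root stay ≤ a). The
adaptive method is the recommended default for island-associated data.
Hulls are sorted by enclosed-point count (descending, ties by area
ascending) and unioned cumulatively until each requested fraction of
points is enclosed; because lower levels are prefixes of higher ones,
nesting is structural, not numerical. Both the 0.10 and 0.25 levels are
commonly called "core"; the package produces whatever levels are
requested and hard-codes neither.

Degenerate hulls (collinear or duplicated points) get zero area and stay
in the ordering rather than being dropped. Time weighting is reserved in
the interface (`s`) but only `s = 0` is accepted.

Union areas and centroids are computed by a boundary-fragment algorithm:
edges are split at crossings with other hulls, fragments interior to
another hull are discarded (coincident duplicates kept once, seams
dropped), and Green's-theorem line integrals over the surviving
fragments give area and first moments. This is exact to floating point —
the test suite checks agreement with an independent geometry library to
1e-6 relative — and handles the duplicate and shared-edge hulls that
LoCoH produces routinely.

The adaptive-a selection rule is implemented as published: the smallest
candidate a whose outer (default 0.95) isopleth has no gaps while
overlapping land by at most 1% of its area. "No gaps" is evaluated on a
raster overlay (default 120 cells per axis) as zero interior holes *and*
a single connected part — a fragmented surface is a gapped surface; the
isopleth area itself is exact, not rasterised. Offshore loops are
excluded purely by depth: maximal runs of fixes over water deeper than
4,000 m are removed in full, with no manual judgement of what counts as
an "obvious" loop.

# Residency metrics

All day-based metrics use the local calendar day at UTC−10 (the study
region), configurable everywhere.

* **Monitoring windows** per transmitter–receiver pair intersect receiver
  deployment, transmitter life (activation to nominal battery end — the
  zero-battery-failure assumption) and the analysis period, counting the
  distinct local days touched.
* **Visits** are segmented by a chronological scan that closes the open
  visit when the receiver changes (at the moment of change, even within
  the gap window) or when a gap of ≥ 30 minutes occurs. Single-detection
  visits are assigned 7.7 min: the longest pulse train (3.6 s) bracketed
  by two maximum silences (230 s), 463.6 s, rounded to one decimal. The
  constant is based on the slowest duty cycle and applied to all
  transmitters to avoid biasing faster-cycling tags toward shorter
  visits.
* **SFI** (Site Fidelity Index) is days detected over monitored days as
  a percentage; an SFI of p% is equivalent to one visit every 100/p days
  under uniform spacing.
* **Summaries** follow the published conventions exactly: mean SFI and
  mean visits/day exclude zeros; visit-duration means include all visits;
  the most-visited receiver (ties broken by higher SFI) anchors
  inter-visit absence durations.

# Temporal patterns

Distinct individuals are counted per pooled hourly or monthly bin (a
shark detected in hour 9 on many days counts once; a per-day variant is
exposed as a flag). The test against "no temporal structure" is a
two-sample Kolmogorov–Smirnov comparison of the n observed bin counts
against n copies of their mean. This mean-as-sample null is a faithful
reimplementation of a published convention and is kept for
comparability; it is statistically unusual and markedly anticonservative
(scatter around the mean alone inflates D), so p-values from it should
be read as a screening device, not calibrated error rates. D is computed
from the pooled ECDFs (tie-aware); p uses the exact conditional
distribution for ≤ 12 bins and the asymptotic Kolmogorov series
otherwise.

# Hurdle tables and model support

Detection data from arrays wider than individual home ranges are heavily
zero-inflated, so presence/absence and non-zero fidelity are prepared as
separate tables: a binary table over all shark–receiver pairs with a
log-listening-days offset, and a proportional table of detected pairs
with (days detected, days not detected) as a binomial response.
Continuous predictors (tagging-site–receiver distance, receiver depth,
total length) are mean-centred and scaled, with the constants kept for
back-transformation. The accompanying declarative model specification
lists fixed effects, the sex×depth and distance×depth interactions
(marginality enforced), random intercepts for transmitter and receiver,
and family/link per component; the offset enters the binary half on the
logit scale as specified in the source convention, which we note is
unusual for a binomial link and emit as stated. The mixed-model fits
themselves are the business of standard engines (`lme4::glmer`,
`gamm4`/`mgcv` with basis dimension 5 for smooths) and are deliberately
not reimplemented; `rank_models_aicc()` supports the standard
small-sample information-theoretic ranking (ΔAICc < 2 support rule,
Akaike weights).

Collinearity is screened with pairwise Pearson correlations and VIFs
from ordinary least-squares regressions of each predictor on the others;
singular designs report infinite VIF with a flag.

# Numerical choices and problem sizes

* Great-circle radius 6,371 km; UTM zone 4; all areas reported in km²
  after projection.
* Bathymetry lookup is bilinear in the four surrounding cell centres,
  exact at centres; nodata neighbours fall back to the nearest valid
  cell with a warning. Raster I/O uses the plain-text ESRI ASCII grid
  format. Depth-profile bins default to 50 m steps from 0 to 1,000 m
  plus an overflow bin — the published depth-frequency figures show a
  50–100 m mode but do not print their edges — and group means and
  standard errors are computed across sharks, not pooled fixes, with
  n = 1 groups flagged and given SE 0.
* The parameter-recovery simulations used throughout the tests run a
  5,000-step walk at 30-minute steps (attraction 0.5/h, step noise
  0.5 km, speed cap 4.2 km/h), thinned to every fifth position for hull
  construction; these sizes give stable recovery (core-isopleth centroid
  within 2 km of the programmed centre, SFI within three binomial
  standard errors of the programmed daily visiting probability) while
  keeping a full test run in a couple of minutes on one core.
* Geometry tolerances are relative (1e-9 of the coordinate scale);
  boundary membership counts as enclosed.

# Worked example

```{r example, eval = FALSE}
island <- tibble::tibble(name = "Moku", lat = 20.8, lon = -156.6,
                         land_radius_km = 15, shelf_width_km = 12)
grid <- generate_seascape(island, resolution = 0.01)

params <- movement_params(center_lat = 20.95, center_lon = -156.45,
                          attraction_per_h = 0.5, noise_km = 0.5)
track <- simulate_shark_track("S1", params, grid, duration_days = 104,
                              step_min = 30, seed = 11)

fixes <- simulate_argos_fixes(track, seed = 12)
filtered <- filter_argos(fixes, reference = c(20.95, -156.45), grid = grid)
planar <- project_to_planar(argos_retained(filtered))

hulls <- locoh_hulls(planar, method = "a", value = 20000)
iso <- build_isopleths(hulls, levels = c(0.10, 0.25, 0.50, 0.95))
tidy(iso)
autoplot(iso)
```

# Known limitations

* The simulator's surfacing process is independent per step; real
  surfacing is bursty, so Argos fix clustering in time is milder here
  than in field data.
* The a-selection gap diagnostics are raster-based; pathologically thin
  isopleth necks below the raster resolution can be misread. Increase
  `raster_n` when the 0.95 surface is filamentous.
* The KS null construction is retained from the source convention and is
  anticonservative (see above).
* Hurdle tables are model-ready inputs; the package does not check that
  a downstream mixed-model engine converges.
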