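# dcmorph

Quantitative analysis of dermal condensate morphogenesis.

Dermal condensates are the fibroblast aggregates that form beneath
hair-follicle placodes and mature into the dermal papilla, the permanent
mesenchymal signalling centre of the hair follicle. A local increase in
cell density can arise by (i) locally increased proliferation, (ii)
directed cell migration, or (iii) failure of cells to disperse. dcmorph is
an R toolkit for telling these mechanisms apart in 3D/4D imaging data — and
for anyone who needs its individual pieces: cell-track motility metrics,
circular statistics, spatial point-pattern tests, or 3D nuclear
morphometry.

## What it computes

**Track analysis** — translational drift correction against non-motile
reference cells; per-track velocity (track length / duration), net velocity
(displacement / duration), straightness (displacement / track length), and
the escape angle

&nbsp;&nbsp;&nbsp;&nbsp; cos α = (a · b) / (|a| |b|)

between a cell's net displacement **a** and the vector **b** from its start
to the condensate centre (0° = straight toward the centre); grouping of
tracks by initial distance (far/near of 30 µm) and optional truncation at
condensate entry.

**Circular statistics** — Rayleigh Z test (Z = nR̄²), two-sample Watson U²
with permutation or exact p-values, and a Monte-Carlo test of the correct
3D null for escape-angle magnitudes (isotropy ⇒ cos α ~ Uniform(−1, 1)).

**Scene analysis** — cell density per region (cells per 10⁴ µm³) with
identical-volume paired comparisons, radial shell densities around beads,
point-to-surface distances (meshes, masks, points), nearest-neighbour label
composition with a χ² randomness test, marker fractions with exact binomial
CIs, four-way cell-cycle-reporter scoring.

**Morphometry** — per-nucleus volume, surface area from a triangulated
isosurface (marching tetrahedra, anisotropy-aware), Wadell sphericity
π^⅓(6V)^⅔/A, region mean intensities, normality-gated group comparisons.

**Assay statistics** — the Shapiro–Wilk-gated t / Mann–Whitney / ANOVA
policy, one-sample ratio tests, scratch-wound closure, relative transwell
migration, ΔΔCt fold changes.

**Synthetic data** — an agent-based simulator of the three condensation
mechanisms (plus an unbiased null), point-scene and label-volume
generators, and drift injection, so every stage above is testable with no
external data.

## Worked example

Simulate a migration-driven condensation, correct drift, and test whether
initially-distant condensate candidates move inward:

```r
library(dcmorph)

cfg <- simulation_config("migration", seed = 42)
sim <- simulate_condensation(cfg)
sim$tracks
#> <track_table> 1507 tracks, 60280 rows, frames 0..39
#>   classes: dc_candidate=674, interfollicular=826, reference=7
#>   markers: sox2, fucci_g1, fucci_sgm, tdtomato, edu

tracks <- correct_drift(sim$tracks)
center <- estimate_dc_center(tracks)          # Sox2+ final-frame centroid
m <- compute_track_metrics(tracks, center)
g <- group_by_initial_distance(m)
vapply(g, function(d) median(d$escape_angle_deg, na.rm = TRUE), numeric(1))
#>          dc_far         dc_near interfollicular
#>             9.4            24.6            66.8

far <- g$dc_far$escape_angle_deg
sphere_uniformity_test(angle_sample(far[!is.na(far)], "axial_magnitude"),
                       seed = 1, alternative = "inward")
#> mean cos(alpha) = 0.98197, p = 9.999e-05 (n = 535)
#>   Monte-Carlo null (cos ~ U(-1,1)), 10000 draws, seed 1, alternative inward
```

Cells starting more than 30 µm from the condensate centre migrate almost
straight toward it (median escape angle 9°, versus 67° for interfollicular
controls — an isotropic walker would show 90°), and the one-sided
spherical-uniformity test rejects isotropy. Running the same pipeline on a
`"proliferation"` or `"nondispersal"` simulation instead flags the
cell-cycle signature or nothing at all — see `run_pipeline()` and its
signature flags.

Worked example on published counts — the fraction of condensate cells
carrying a lineage label induced one day earlier, 53 of 82 cells:

```r
lf <- label_fraction(53, 82)
#> 64.6% (95% CI 53.3–74.9%)
```

## Package layout

- `R/` — simulator, track/trajectory analysis, circular stats, scene
  analysis, morphometry, assay stats, pipeline orchestration, file I/O
  (track CSV with TrackMate-style remapping, scene JSON, multi-page TIFF
  volumes, OBJ meshes, YAML run configs).
- `tests/testthat/` — unit and property tests per module plus an
  end-to-end acceptance suite.
- `vignettes/condensate-analysis.Rmd` — the methods vignette: models,
  parameter choices, numerical decisions, limitations.
- `inst/cli/dcmorph.R` — thin command-line wrapper (`simulate`, `run`).
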