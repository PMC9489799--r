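# aggremorph

Morphometry of soluble protein aggregates from single-molecule localization
microscopy.

Small soluble aggregates of amyloid proteins such as α-synuclein — not the
mature fibrils — are increasingly implicated as the toxic species in
neurodegenerative disease. Transient-binding super-resolution imaging
(thioflavin-X or aptamer DNA-PAINT) can size individual aggregates well
below the diffraction limit, but turning raw localization tables into
per-aggregate sizes and population comparisons takes a chain of analysis
steps that is usually scattered across plugins and scripts. `aggremorph`
packages that chain for R users: localization simulation with ground truth,
spot fitting and quality filtering, fiducial drift correction, density-based
clustering, per-aggregate morphometry, and two-sample distribution
comparison, plus the companion diffraction-limited quantifications
(per-liposome Ca²⁺ influx and single-molecule pulldown spot counting).

## The analysis chain

1. **Localization** — candidate spots (local maxima above the frame median
   plus *k* robust SDs) are fit with a pixel-integrated 2D Gaussian on a 7×7
   ROI. Each fit's precision uses the Thompson closed form
   σ²\_loc = (s² + a²/12)/N + 8π s⁴ b /(a² N²), with *s* the PSF SD, *a* the
   pixel size, *N* the photons and *b* the background.
2. **Filtering** — keep rows with intensity ≥ `min_signal` and precision ≤
   `max_precision`. Presets: `"thx"` = 100 photons / 20 nm, `"paint"` = 60
   photons / 40 nm.
3. **Drift correction** — fiducial beads are tracked frame to frame; the
   per-frame mean bead displacement from frame 0, smoothed by a moving
   average, is subtracted from every localization.
4. **Clustering** — DBSCAN over the pooled localizations. A point is *core*
   iff its closed ε-ball holds ≥ minPts points; clusters are
   density-connected core components plus attached border points. Presets:
   ε = 75 nm / minPts 9 (`"thx"`), ε = 200 nm / minPts 10 (`"paint"`). The
   grid-indexed implementation is verified against a quadratic reference
   (`dbscan_brute`) in the tests.
5. **Morphometry** — per cluster: length *L* = max pairwise distance of the
   member localizations (max Feret diameter) and eccentricity
   *e* = √(1 − λ₂/λ₁) from the second-moment eigenvalues λ₁ ≥ λ₂, i.e. the
   focal-distance / major-axis ratio of the moment ellipse (0 = circle,
   1 = line/fibril). An optional correction subtracts the ~2×precision
   noise inflation of *L*.
6. **Comparison** — unit-mass histograms on shared edges, ECDFs, their
   difference curves with the largest cumulative excursion, a two-sample
   Kolmogorov–Smirnov test (asymptotic p at √(nm/(n+m))·D) and a
   Mann–Whitney U test (exact null enumeration for n·m ≤ 400 without ties).

For the liposome assay, per matched spot across the background / sample /
ionomycin conditions,

    Ca²⁺ influx % = 100 · (F_sample − F_background) / (F_ionomycin − F_background)

with ionomycin defining full permeabilization; the ratio is invariant under
common affine intensity rescalings, so camera baselines cancel.

## Worked example

Simulate a 100-aggregate rod population with a 190 nm median length
(the "20% fraction" preset), push it through the chain, and compare it to a
390 nm population:

```r
library(aggremorph)
set.seed(1)
cfg    <- analysis_config(preset = "thx")
params <- scenario_preset("fraction20", n_aggregates = 100L)
locs   <- simulate_localizations(sample_aggregates(params), params)
nrow(locs)
#> [1] 19858
kept   <- filter_localizations(locs, cfg$min_signal, cfg$max_precision)
labels <- dbscan_cluster(kept, cfg$eps, cfg$min_pts)
labels
#> DBSCAN labeling: 7344 points, 100 clusters, 285 noise (eps 75, minPts 9)
summarize_sample(kept, labels)
#> Aggregate morphometry: 100 clusters, median length 248.1 nm,
#>   mean length 251.0 nm, mean eccentricity 0.94
```

All 100 aggregates are recovered; the raw median (248 nm) sits above the
190 nm ground truth because localization noise inflates the max Feret
diameter — `summarize_sample(..., correct_length = TRUE)` applies the
documented first-order correction. Comparing against a `"fraction50"`
population (median 390 nm) simulated the same way:

```r
compare_groups(morpho$records$length, morpho_b$records$length,
               bin_width = 10, names = c("20%", "50%"))
#> Distribution comparison: 20% (n=100) vs 50% (n=100)
#>   medians: 248.14 vs 421.27
#>   KS D = 0.8300, p = 2.41e-30
#>   Mann-Whitney U = 341.0, p = 5.11e-30
#>   largest cumulative difference 0.830 at 317.2
```

The smaller population is cleanly separated: the cumulative length
distributions differ most (excursion 0.83) at ~317 nm, between the two
medians, and both tests reject equality. `run_pipeline()` wires the same
stages together behind one seeded call and writes the localization tables,
morphometry CSVs, a comparison JSON and a run manifest;
`inst/scripts/aggremorph.R` is a thin command-line wrapper around it.

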