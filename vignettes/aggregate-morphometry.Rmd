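---
title: "Measuring protein-aggregate morphology from localization microscopy"
author: "aggremorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring protein-aggregate morphology from localization microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggremorph)
```

## The measurement problem

Transient-binding localization microscopy (thioflavin-X imaging or aptamer
DNA-PAINT) resolves individual soluble protein aggregates far below the
diffraction limit: a dye or imager strand binds an aggregate briefly, is
localized as a single molecule, and over thousands of frames the
accumulated localizations trace out each aggregate. The scientific readout
is per-aggregate morphology — length and eccentricity — and how the
morphology *distribution* differs between two populations (e.g. aggregate
preparations of increasing fibril content, or patient-derived versus
control brain extracts). This vignette describes the models and numerical
choices behind each stage of the chain `aggremorph` implements, and what
the package's synthetic data do and do not establish.

## Localization model and fitting

Diffraction-limited frames are modelled as a constant camera baseline plus,
per emitter, a pixel-integrated 2D Gaussian whose total volume is the
photon count, with per-pixel Poisson noise. Fitting inverts exactly this
model: candidates are strict 3×3 local maxima above the frame median plus
`detect_threshold_k` (default 5) robust noise SDs (scaled MAD); maxima
within 3 pixels keep only the brighter; each candidate is fit on a 7×7
pixel ROI. The nonlinear search runs over center and log-sigma only — for a
fixed shape the amplitude and baseline enter linearly and are solved by QR
in closed form — which keeps the optimization 3-dimensional, fast and free
of amplitude/baseline initialisation problems. Fits that leave the ROI,
fail to converge, or return non-positive photons are dropped.

Each fit's localization precision uses the Thompson closed form

$$\sigma_{loc}^2 = \frac{s^2 + a^2/12}{N} + \frac{8\pi s^4 b}{a^2 N^2},$$

with $s$ the fitted PSF SD, $a$ the pixel size, $N$ the photons and $b$ the
fitted per-pixel background (a Poisson variance proxy). A closed form was
chosen over Cramér–Rao integration because it is deterministic and cheap;
the tests verify that on Poisson-noise spots at 1000 photons the actual
RMSE agrees with the predicted precision within a factor of two, which is
the accuracy class this estimate needs for its only downstream use:
quality filtering.

Filtering keeps rows with intensity ≥ `min_signal` and precision ≤
`max_precision`. The two presets bundle the field's standard settings —
`"thx"` (100 photons, 20 nm, with DBSCAN ε = 75 nm, minPts 9) and
`"paint"` (60 photons, 40 nm, ε = 200 nm, minPts 10). The original
plugin's "signal strength" is a composite quantity with no public
definition; here it is interpreted as the fitted photon count, and the
threshold is configurable precisely because that interpretation is ours,
not a published fact.

## Drift correction

Stage drift over a 6000–8000-frame acquisition is measured against bright
fiducial beads. Each bead is *tracked*: its frame-0 localization anchors
the track, and every subsequent frame is matched to the nearest
localization within `search_radius` (default 500 nm) of the *previously
tracked position*. Tracking (rather than matching against a static
reference) matters once cumulative drift becomes comparable to the bead
spacing or the radius — with several hundred nm of drift a static matcher
can lock onto a neighbouring bead. The per-frame mean bead displacement is
interpolated across gaps, smoothed by a centred moving average
(`smooth_window` = 100 frames, shrinking at the edges), re-anchored so the
trajectory is exactly (0, 0) at frame 0, and subtracted from every
localization; matched bead rows are removed. For a linear drift the
centred average is exact in the interior and biased only within half a
window of the ends, which is what bounds the residuals the tests check
(< 2 nm with noiseless beads, < 10 nm of residual per-frame motion with
10 nm bead noise, under 400 nm of total drift).

## Clustering conventions

Aggregates are recovered by DBSCAN over all pooled localizations (pooling
across frames is the standard choice for transient-binding data, where one
aggregate yields localizations in many frames). The conventions, which
textbook variants differ on, are fixed as:

* neighbourhoods are **closed** ε-balls **including the point itself** —
  the convention of the common library implementations;
* border points reachable from several clusters join the cluster of their
  **first core neighbour in ascending row order** (the original analyses
  inherit an unspecified order dependence; this makes it deterministic);
* cluster ids are assigned **in order of first member row**, so output
  files are reproducible.

The production implementation indexes points on a uniform grid of cell
size ε (neighbours live in the 3×3 surrounding cells) and is written in
C++; a pure-R $O(n^2)$ neighbourhood-graph implementation, `dbscan_brute`,
is kept in the package as the independent reference. The test suite and
the acceptance script require *exact* partition agreement between the two
on hundreds of random instances (n ≤ 300, ε ∈ {25, 75, 200} nm,
minPts ∈ {3, 9, 10}), alongside order-invariance of the core partition and
monotonicity of the noise count in ε.

## Morphometry

With member localizations $p_1 \dots p_n$:

* **eccentricity** comes from the second central moment matrix with
  eigenvalues $\lambda_1 \ge \lambda_2$: $e = \sqrt{1 - \lambda_2/\lambda_1}$.
  For an ellipse this is exactly focal distance over major axis (0 =
  circle, 1 = line, i.e. fibrillar), so moments recover the quantity
  without any boundary-ellipse fit. Degenerate cases are pinned down:
  coincident points measure 0, and a 2-point cluster measures exactly 1.
* **length** is the maximum pairwise distance (max Feret diameter), chosen
  for robustness and for monotonicity under adding points. The
  projection extent along the major axis is available via
  `metric = "extent"`. Which of these the original toolkits report is not
  recoverable from public descriptions; Feret is the documented default.

Localization noise *inflates* the Feret diameter: each of the two extreme
points carries ~1× precision of outward noise, and the maximum over many
point pairs grows slowly (like $\sqrt{2\log n}$) with the localization
count. `summarize_sample(..., correct_length = TRUE)` applies the
first-order correction $L_c = \max(0, L - 2\bar\sigma)$ with $\bar\sigma$
the cluster's mean precision. The default output is **raw** — matching how
such measurements are reported in practice — but analyses that compare
against *known ground truth* (the recovery checks in the tests and the
acceptance script) use the corrected estimator, because at 20 nm precision
the raw inflation is comparable to the size of small aggregates and would
otherwise dominate the comparison: for ~50-nm-scale aggregates it shifts
measured medians by tens of nm and relocates distribution-difference peaks
accordingly. The tests bound the raw bias explicitly (positive, of order
2–3× the precision at 50–150 localizations per cluster).

Rendering (`render_superres`) is a localization histogram at a chosen
pixel size convolved with a unit-mass Gaussian kernel; the image integral
equals the localization count except for mass blurred across the border
(zero-padded convolution — the only edge effect).

## Population comparison

`compare_groups` builds unit-mass histograms on shared edges (default bin
width 10 nm for lengths), both ECDFs on the pooled support, and their
difference curves with the location and value of the largest absolute
cumulative excursion. The sign convention is (a − b) throughout: negative
differences mean the feature is more abundant in group b. Tests:

* **Kolmogorov–Smirnov**: $D = \sup |F_a - F_b|$ over the pooled values;
  p from the asymptotic Kolmogorov distribution at $\sqrt{nm/(n+m)}\,D$.
  Samples here are thousands of aggregates, so small-sample exactness is
  deliberately out of scope.
* **Mann–Whitney**: $U = \#\{x_i > y_j\} + \tfrac12\#\{x_i = y_j\}$,
  reported as $\min(U, nm-U)$. For tie-free data with $nm \le 400$ the
  two-sided p is exact, from the enumerated null distribution of $U$ (the
  standard count recursion); otherwise the normal approximation with tie
  and continuity corrections is used. The tests verify the exact branch
  against brute-force enumeration of all $\binom{n+m}{n}$ assignments.

## Companion assays

**Liposome Ca²⁺ influx.** Three co-registered 50-frame stacks (background,
sample, ionomycin) are frame-averaged; spots are detected independently
per condition and matched by mutual nearest neighbour within two
diffraction-limited pixels (474 nm); per matched spot the influx
percentage is $100\,(F_s - F_b)/(F_i - F_b)$, with $F$ the integrated
aperture intensity. Because the ratio is invariant under any common affine
intensity transform, the camera baseline cancels and no background
subtraction is needed. Values are *not* clamped to [0, 100]: noise can
produce small negatives, and clamping would bias field-of-view means.
Spots with $F_i \le F_b$ (unresponsive liposomes) are flagged and excluded
from the mean.

**Spot counting.** Diffraction-limited and single-molecule-pulldown fields
are counted as local maxima above an intensity threshold calibrated
against a negative control: the smallest threshold whose mean control
count per field does not exceed a budget (default 2 spots/field — the
published procedure is qualitative, so the budget is an explicit
parameter). Specificity is the ratio of mean per-field counts between a
target antibody and its isotype control. Responses are normalized either
linearly between negative- and positive-control means (0–100%) — the
published normalization formula being unstated, this linear map is the
recorded interpretation — or by a per-sample total-protein scalar.

## What the generator emulates — and what it does not

`scenario_preset` fixes the study conditions the synthetic data emulate:

| preset | median length | spread (log-SD) | shapes | field |
|---|---|---|---|---|
| fraction20/30/40/50 | 190/240/290/390 nm | 0.25 | rods | 100 µm, 300 aggregates |
| pd_brain / hc_brain | 55 / 68 nm | 0.5 | 50% rods, 50% disks | 450 µm, 6000 aggregates |

Lengths are lognormal — the published summaries give means/medians but not
a family, so this is a modelling choice; log-SD 0.5 for the brain presets
puts most aggregates below 100 nm with a heavier tail in the control
group, as that data shows. Binding kinetics are collapsed to an
independent per-site per-frame Bernoulli event (`p_bind`, default 4×10⁻⁴;
1.2×10⁻³ for the fraction presets so that clusters retain ≥ 50
localizations after the 100-photon/20-nm filter): dwell-time structure is
irrelevant to morphometry. Sites sit every 10 nm along rods (uniform
lateral jitter across a 10 nm width, a protofilament-scale cross-section)
or uniformly over disks. Localization noise is isotropic Gaussian with
σ = 20 nm; photons are exponential with mean 1000 (the heavy tail typical
of single-molecule intensities), and the recorded precision
$\sigma\sqrt{\bar N/N}$ gives the filter realistic variation around 20 nm.
Background false localizations arrive at 10⁻⁵ µm⁻²frame⁻¹, a post-filter
residual rate. The brain presets use one large synthetic field at sparse
surface density (~0.03 µm⁻²) as the equivalent of many pooled fields of
view; at that density the chance of two aggregates falling within one
ε = 200 nm reach of each other (and being merged) is ~2%.

Not emulated: blinking-state photophysics, spectral crosstalk, 3D PSFs,
dwell-time distributions, liposome tethering geometry, and any
non-uniformity of the illumination. Consequently, passing tests establish
that the *analysis chain* is correct and self-consistent under the stated
noise model — they do not certify performance on real data whose
photophysics violate these simplifications.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations to
desk-scale runs: 200 random DBSCAN instances of up to ~330 points, 300
aggregates per fraction preset, ~5000 measured aggregates per brain-like
group, 100 liposomes per influx field (10 fields), 8000-frame drift
tracks, and 10⁴-point ellipse samples. One seeded generator drives every
stage; no stage reseeds from time, and writers emit fixed-format text, so
a fixed seed reproduces localization tables, morphometry CSVs and
comparison reports byte for byte — an invariant the tests check with file
digests.

## Known limitations

* Lengths below ~2× the localization precision are dominated by noise
  inflation; even corrected values for 20–40 nm aggregates are
  semi-quantitative.
* The KS p-value is asymptotic only; do not use it for samples of a few
  dozen aggregates.
* Eccentricity of clusters with few localizations is biased upward (a
  2-point cluster is a line); interpret population means, not single
  small clusters.
* The drift tracker assumes per-frame drift steps far below the search
  radius and at least one bead visible in frame 0.
* Mutual-nearest-neighbour spot matching assumes the three influx
  conditions image the same positions to within two pixels; larger
  registration errors need an alignment step out of scope here.
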