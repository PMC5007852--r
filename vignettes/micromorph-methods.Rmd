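---
title: "Automated microglial morphometry: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated microglial morphometry: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(micromorph)
```

## The problem

Microglia — the resident immune cells of the brain — remodel their shape when
they activate: a resting cell is ramified, with a small soma and long thin
processes, while an activated cell retracts its arbor and becomes rounder and
larger-bodied.  Quantifying that transition from confocal fluorescence imagery
by hand is slow and biased, so this package implements an automated pipeline:

1. **simulate** fluorescence z-stacks with known per-cell ground truth,
2. **segment** cells from the 2D maximum-intensity projection (MIP) by
   regional-maxima seeding and iterative-threshold mask growth, with
   post-segmentation QC and soma extraction,
3. **measure** six shape parameters per cell — cell area, soma area,
   perimeter, cell spread, eccentricity, roundness,
4. **test** group differences after normalizing each (region, parameter)
   stratum to its control mean (one-way ANOVA, Bonferroni post hoc), and
5. quantify the ancillary scalar assays: phagocytic index, colocalization
   counts, flow-gate fractions, urine-marking preference and the
   social-interaction quotient.

Because no raw imagery ships with the package, the synthetic generator is a
first-class module: every quantitative claim made by the test suite is checked
against exact, recomputable ground truth.

## The synthetic scene model

A scene is a (z, y, x) stack, by default 10 optical sections 1 µm apart at
0.42 µm/pixel over a 512×512 field — typical confocal acquisition settings for
microglia.  Cells are drawn per regime:

* **resting** (ramified): elliptical soma of radius 6 px (≈2.5 µm), axis
  ratio 1.25, five primary processes grown as heading-diffusing random walks
  of 30 px (≈12.6 µm), recursively branching with probability 0.5 down to
  depth 2; process thickness 3 px tapering to ~2 px at the tip (≈1 µm,
  realistic at this magnification).
* **activated** (amoeboid): soma radius 1.3× the resting value (7.8 px; the
  soma *area* therefore scales by 1.69), two short stubs of 12 px, no
  branching.

Processes carry 0.7 of the soma intensity: microglial processes are genuinely
dimmer than somas in projection (smaller fluorophore volume per pixel), and
the gap is what lets a fractional intensity threshold isolate the soma.  Cell
positions are rejection-sampled with a minimum soma spacing of 55 px; each
cell's pixels are owned exclusively by one label, so ground truth stays exact
even where arbors touch.  Per-cell size jitter is lognormal with CV 0.1.

Rendering places each cell on a random home section and lets it bleed into
the two neighbouring sections with a Gaussian axial falloff (σ = 0.8
sections), plus a mild 1 %-per-section attenuation — an approximation of
confocal sectioning without a full PSF model (no lateral PSF, no
photobleaching; truth is defined at projection level, matching the 2D MIP
analysis).  Noise is Poisson shot noise on the signal (gain 0.2
photons/intensity unit) plus additive Gaussian background.  The scene SNR —
(peak soma intensity − background mean)/background sd — defaults to 8.
Neither the cell density nor the SNR of the original acquisitions is known;
30 cells per field at SNR 8 are fixture choices, roughly 650 cells/mm², a
realistic cortical density.

What the generator does **not** emulate: overlapping cell territories,
intensity heterogeneity within a compartment, out-of-focus haze, vascular
shadows and staining artifacts.  Passing the recovery tests therefore shows
the algorithm is correct and robust to shot/read noise at realistic contrast,
not that it would meet the same quality bars on arbitrary real tissue.

## Segmentation

All analysis runs on the MIP.  Seeding uses the h-maxima transform
(morphological reconstruction by dilation of `image − h` under `image`,
implemented in C++ since no installed R package exposes greyscale
reconstruction) on a Gaussian-smoothed copy (σ = 2 px).  Regional-maxima
plateaus of the transform become seeds at their centroids.  Three filters
follow: prominence `h` (20 % of the smoothed dynamic range — deep enough that
smoothed intensity bumps where processes widen or branch do not seed, while
somas keep several times this prominence), a minimum seed intensity (50 % of
the smoothed dynamic range above the smoothed minimum, same rationale), and a
minimum seed separation of 10 px keeping the brighter seed.

Mask growth uses a single quantized threshold ladder shared by all seeds,
stepping down from the image maximum in 5 %-of-dynamic-range steps.  A seed
activates at the first level at or below its peak; its mask at each level is
the connected component containing it.  Growth stops when

* (a) the component would absorb another seed — the mask falls back to the
  previous level, or
* (b) the area grows by more than 8× in one step **and** the increment
  exceeds the maximum plausible cell area (the upper area bound) — flooding;
  ramified cells legitimately jump ~5–6× in one step when the ladder crosses
  the process intensity, while true floods add far more area than any cell,
  which is why a bare growth-ratio rule cannot have a tight default, or
* (c) the ladder reaches the noise floor — a robust background estimate
  (median + 2 MAD-sd of the image); thresholding inside the noise floor only
  fattens masks with background chains.

Because every final mask is a connected component at some ladder level and
rule (a) fires at the merge level, masks of different seeds are **provably
pairwise disjoint** — no contested-pixel tie-break is ever needed.  A seed
whose first active level already floods (a seed on background) is flagged
with an empty mask.  Interior holes (noise pixels below threshold inside a
cell) are filled.

QC then rejects masks that are empty, multi-component, contain more than one
seed (multi-soma), fall outside the area bounds [50, 5000] px², or touch the
2 px border margin; every rejection carries a reason code, and accepted-cell
counts are validated against brute-force counts of known placements.

The soma is extracted on the *smoothed* MIP: within the cell mask, pixels
above background + 0.6 × (seed peak − background) form the soma component.
Smoothing attenuates thin processes geometrically (a 3 px ribbon keeps ~40 %
of its amplitude under σ = 2 smoothing, a soma keeps ~99 %), so the
fractional threshold separates soma from processes even though raw process
intensity is 0.7 of the soma.  Measuring the threshold from the background
rather than from zero keeps the cut at the soma's geometric boundary.

## Morphometric parameters

For each accepted cell (masks in full-frame coordinates; R's native 1-based
(row, column) indexing):

* **cell area / soma area** — pixel counts × pixel size².
* **perimeter** — closed Moore-neighbour boundary tour of the hole-filled
  mask, axial steps weighted 0.948 and diagonal steps 1.340 (the classical
  near-unbiased weights for digital contours; naive pixel-edge counting
  overestimates smooth outlines by 4/π and would bias roundness badly).
  Single-pixel masks use the 4-step convention.
* **cell spread** — mean Euclidean distance from the mask's center of mass to
  its eight extremal points (two per cardinal side, the standard extrema
  convention).
* **eccentricity** — major/minor axis ratio of the moment-based best-fit
  ellipse (square-rooted eigenvalue ratio of the second central moment
  matrix), reported ≥ 1; a circle gives 1.  The underlying verbal definition
  ("smallest circle fitting the extensions") is not self-consistent, so the
  moment ellipse is used as the standard interpretation.  Degenerate
  one-pixel-wide masks give an infinite, flagged value and are excluded from
  statistics.
* **roundness** — 4π·area/perimeter²; 1 for a circle.  Because the digital
  perimeter can slightly undershoot for near-disks, values above 1 are
  clipped and flagged; unclipped stored values satisfy the defining identity
  to 1e-9.

Every parameter is validated against an independent brute-force pixel-loop
oracle (direct scans, a separately written boundary walk, closed-form
eigenvalues) to 1e-9, and lengths/areas scale correctly under pixel-size
changes while the dimensionless descriptors stay fixed.

## Group statistics

Cells within one imaged field share that field's acquisition and are treated
as pseudo-replicates: the analysis unit is the per-field (per-animal) mean,
the mean-per-animal design standard in this literature.  Values are
normalized per (region, parameter) stratum to the control-group mean
(control ≡ 100 %); strata without a usable control are excluded and flagged.  Each stratum gets a one-way fixed-effects ANOVA (via `stats::lm`;
an independent sum-of-squares computation serves as the test oracle) followed
by classical Bonferroni post hoc tests: pooled-MSE t statistics on the
within-group degrees of freedom, raw p × m capped at 1 (not Welch — matching
the reporting conventions the pipeline emulates; the six parameters are
treated as independent measures, so no cross-parameter correction).
`anova_from_summary()` reconstructs the same F from printed mean ± SEM and n,
which round-trips raw balanced data exactly.  Spearman correlation is Pearson
on average ranks with the t approximation for p.

Simulation checks: the ANOVA's type-I error stays at its nominal 5 % over 500
null datasets, and an activated-like vs resting-like contrast (6 fields per
group through the full pipeline) yields Bonferroni-significant increases in
roundness and soma area with decreased perimeter, while two same-regime
groups show no significant differences — the qualitative activation pattern
the morphometry is designed to detect.

## Scalar assays

* **Phagocytic index** — engulfed-particle area ÷ total cell area; only
  particle signal inside cell masks counts ("phagocytosed" = engulfed
  overlap).
* **Colocalization count** — cells whose soma centroid lies inside the marker
  mask (threshold-overlap alternatives were considered; the centroid rule is
  exact, monotone under marker dilation, and robust to marker speckle).
* **Flow-gate fraction** — rectangular parent/child thresholds on transformed
  intensities (transform the event table first — e.g. log or asinh — with
  thresholds on the same scale; the fraction is invariant to monotone
  transforms applied jointly).  Upstream viability/doublet gates are emulated
  as truth-label pre-filters in synthetic data, not re-derived from scatter.
* **Marking preference** — 100 × (mark pixels inside the target 20 cm circle)
  ÷ (all mark pixels); the four circles sit one per quadrant of the 46 cm
  arena, tangent to the two outer edges.
* **SI quotient** — time in the social-cylinder investigation zone ÷ time at
  the empty cylinder, from per-frame membership.  The investigation zone is
  the annulus within 2 cm of the cylinder wall — the tracking software's
  actual zone definition is not documented anywhere accessible, so the width
  is a configurable choice.

Degenerate inputs (no marks, no object-zone time, empty parent gate, zero
cell area) are flagged or raised, never silently zero.  All five assays
reproduce generator ground truth exactly at pixel/frame/event-count level.

## Determinism and numerics

One top-level integer seed is split per stage and scene by a Lehmer-style
hash (`derive_seed`), all arithmetic below 2³¹; identical (preset, seed)
pairs regenerate scenes bit-identically, and the whole pipeline is
deterministic given its config.  Threshold ladders are quantized from the
image maximum, which is what makes mask disjointness provable; equal-intensity
plateaus in seed detection are treated as one maximum at their centroid.
CSV output is UTF-8 with period decimals at full (17 significant digit)
precision; stacks and label images round-trip losslessly as 16-bit TIFF.

## Problem sizes

The validation suite uses: a standard 512×512, 30-cell, SNR-8 field for
segmentation quality (detection F1 and mask IoU against truth); 200 random
masks for the morphometry oracle; 18 fields for the direction-of-effect
contrast; 500 simulated datasets for the type-I error; and 50–100 random
scenes per scalar assay.  These sizes give stable estimates of every reported
quantity while keeping a full validation run in the minutes range.

## Known limitations

* Touching or overlapping cells are resolved by the absorb rule, not by a
  watershed-style split; heavily overlapping arbors are out of the truth
  regime by design.
* The exact stopping rule of the original iterative-threshold implementation
  is not public; the ladder/floor/flood reconstruction here is validated
  against synthetic truth, not against the original code.
* Perimeter (and hence roundness) carries the usual digital-contour bias for
  very small or one-pixel-wide shapes; QC's lower area bound keeps such masks
  out of the statistics.
* The reconstruction of F statistics from printed mean ± SEM summaries
  assumes the printed group sizes; inconsistent published df cannot be
  repaired from summaries alone.
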