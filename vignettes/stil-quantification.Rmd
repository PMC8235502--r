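---
title: "Quantifying stromal TILs from labeled histology rasters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stromal TILs from labeled histology rasters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stilquant)
```

## Scope and model

`stilquant` computes the stromal tumor-infiltrating lymphocyte (sTIL)
density biomarker for breast-cancer sections and evaluates it against
survival endpoints. The package deliberately splits the problem in two:

* **inference** (telling tumor from stroma, finding cells) is behind a
  backend contract — any classifier that can produce a class-labeled
  raster and a point list plugs in;
* **scoring** (macro-tumor outlining, stroma definition, exclusion rules,
  density, cutpoints, survival models) is deterministic, fully specified
  here, and is what this package implements and tests.

The scoring model assumes a calibrated isotropic raster (µm/px known and
equal in x and y; anisotropic inputs are rejected at load time because no
rule here defines behaviour for them) and one of five exclusive classes
per pixel: background (glass), stroma, tumor, necrosis, non-invasive
epithelium.

## Geometric pipeline and its parameters

| parameter | default | units | role |
|---|---|---|---|
| `kernel_radius_um` | 750 | µm | radius of the circular kernel scoring local accumulated tumor area |
| `tumor_fraction_threshold` | 0.10 | — | minimum local tumor fraction for macro-tumor membership |
| `morph_radius_um` | 250 | µm | disk radius of the closing/opening smoothing the outline |
| `margin_um` | 250 | µm | invasive margin added around the macro tumor |
| `epi_exclusion_um` | 150 | µm | exclusion buffer around non-invasive epithelium |
| `heatmap_radius_um` | 200 | µm | kernel of the local-density heatmap |

The kernel radius, margin, exclusion buffer and heatmap radius are the
published workflow's values. Two quantities the workflow names but does
not fix are exposed as configuration with documented defaults:

* **`tumor_fraction_threshold` = 0.10.** The local-kernel tumor fraction
  must be converted to a membership decision somewhere; 0.10 was chosen
  once so that satellite tumor nests within a kernel radius of the main
  mass merge into one macro region while an isolated single gland (a few
  hundred µm² inside 1.77 mm² of kernel area) does not. Lowering the
  threshold grows the outline monotonically, which is tested.
* **`morph_radius_um` = 250.** The structuring-element size of the
  closing/opening. 250 µm matches the margin scale: gaps narrower than
  500 µm between candidate regions close, protrusions thinner than the
  element open away.

The margin is applied by dilating the *macro-tumor mask*, not the raw
tumor pixels: the invasive margin is defined relative to the tumor border
a pathologist would draw, which is what the macro outline approximates.
A central hyalinized scar has no class of its own; a segmentation backend
must label it `NECROSIS` for the scar exclusion to apply — this is a
documented contract on backends, not a geometric rule.

### Exclusion audit

Every input detection receives exactly one audit code:
`NOT_TIL`, `IN_TUMOR`, `IN_NECROSIS`, `NEAR_EPI`, `OUTSIDE_STROMA`, or
`KEPT`, with the precedence `IN_TUMOR > IN_NECROSIS > NEAR_EPI >
OUTSIDE_STROMA` when zones overlap, so reporting is deterministic. Counts
conserve by construction and the conservation is asserted in the tests.

## Numerical conventions

* **Coordinates.** 0-based pixel indices, x rightward, y downward; a
  point's distances are measured to pixel centers. Sub-pixel centroids
  snap to the nearest pixel center before any mask lookup — the upstream
  workflow does not state a snapping rule, so this one is ours and is
  used consistently by code and oracles.
* **Disk discretization.** A pixel belongs to a disk iff its center lies
  within the radius, boundary inclusive, so the 150 µm rule reads
  "within". All µm radii are converted through the calibration; a radius
  below one pixel is rejected as a calibration mismatch rather than
  silently degenerating.
* **Kernel edges.** The local tumor fraction divides by the in-image disk
  pixel count, not the full disk, so tumor fractions near slide edges are
  unbiased.
* **Convolutions and distances.** Disk counting uses FFT convolution with
  results rounded back to exact integers (numerator and denominator are
  counts); dilation/erosion threshold an exact Euclidean distance
  transform, which makes closing∘opening idempotent (asserted). One
  consequence worth knowing: the opening rounds off sharp convex corners
  (a 90° rectangle corner loses the few pixels outside the inscribed
  disc) — this is the correct behaviour of a disc-structured opening, not
  an artifact.
* **Connectivity.** Connected components are 4-connected.
* **Heatmap denominator.** The local density at a stroma pixel divides
  the TIL count in the 200 µm disk by the *disk ∩ stroma* area, not the
  full disk area; otherwise densities at stroma boundaries would be
  systematically underestimated. Non-stroma pixels carry `NA`. Whether
  the published heatmap restricts its kernel this way is not stated; this
  choice is documented and tested for consistency (the area-weighted
  heatmap mean reproduces the global density).
* **Unrounded densities.** `compute_density()` reports full precision;
  only the CLI rounds for display, so cutpoint comparisons never depend
  on formatting.

## Survival statistics

* **Endpoints.** Overall survival (surgery to death, any cause) and
  relapse-free survival; death without relapse censors RFS, which the
  cohort simulator encodes as `rfs_time = min(relapse, death, last
  visit)`.
* **Kaplan–Meier** uses the product-limit estimator with Greenwood
  variance (via the survival package), verified against explicit
  risk-set bookkeeping in the tests.
* **Cox models** use Efron tie handling (standard, better than Breslow
  under ties; the published analysis does not state its choice).
  Continuous biomarkers are entered as value/10 (manual percent) and
  value/300 (density, cells/mm²) so hazard ratios read as increments of
  10 % and 300 cells/mm². Only complete cases enter adjusted models;
  covariates use the standard codings (age ≥50, size >2 cm, nodes
  0/1–3/≥4, type ductal/lobular/other). A monotone partial likelihood is
  an error by default; adjusted models in the pipeline driver downgrade
  it to a warning because a sparse nuisance factor level (e.g. zero
  events among lobular cases in a small cohort) should not void the
  biomarker estimate.
* **Dichotomization boundaries.** Manual scores use "high iff > 10 %"
  exactly as the guideline states. For the density the boundary side is
  unstated; `≥ cutpoint` is used and the rule is recorded in the output.
* **Maximally selected rank statistics.** Candidates are the observed
  biomarker values whose low-group proportion lies within the 10–90 %
  quantile window (the cited method's settings are not published; the
  window is exposed). For each candidate the signed standardized
  log-rank statistic is computed — all candidates in one pass by ordering
  subjects by biomarker so each high group is a prefix and the per-event
  risk counts become cumulative sums; this is algebraically identical to
  the per-candidate log-rank and tested to be so. The adjusted p-value is
  the improved Bonferroni-type bound
  p ≤ 2(1−Φ(b)) + Σᵢ exp(−b²/2)(tᵢ − (b²/4 − 1)tᵢ³/6)/π, with
  tᵢ = √(1 − mᵢ(n−mᵢ₊₁)/((n−mᵢ)mᵢ₊₁)) over ordered candidate group sizes
  — conservative near b = 0 and flagged "approximate"; an exact
  permutation p-value is available via `p_method = "permutation"`.
* **Concordance** treats the manual high/low status as the reference;
  discrepant cases whose continuous scores lie within configurable bands
  of both cutpoints are flagged as expected borderline disagreement.

## What the synthetic data does and does not emulate

`render_slide()` draws an elliptical tissue region on glass, disc-shaped
tumor blobs with carved-out necrotic cores, DCIS-like blobs placed in
clear stroma, and cells as 4 µm discs in distinct colors: stromal TILs
from a homogeneous (optionally low-frequency-modulated) Poisson process,
dense lymphoid aggregates in a ring around DCIS, decoy TILs inside tumor
and necrosis, and OTHER-class mononuclear cells. Region-overlap claims
resolve with precedence tumor > necrosis > epithelium > stroma. The
point count in any region is exactly Poisson(intensity × area), which the
tests verify over 100 seeds.

Two deliberate simplifications matter for interpreting green tests:

* geometry is circular and texture-free — nothing about real H&E stain
  variation, nuclear morphology, sectioning artifacts, or infiltrative
  growth patterns is represented, so passing tests validate the *scoring
  rules*, not inference on real stains;
* with the default pure-Poisson placement, cells may overlap; a rendered
  pair closer than a cell diameter merges into one component that no
  detector could split. Backend-exactness tests therefore use a spec with
  a minimum spacing (Matérn-II thinning, ground truth = retained
  points), while intensity-recovery tests use spacing 0 so the realized
  intensity equals the nominal λ.

`simulate_cohort()` draws a log-normal density biomarker (median 400
cells/mm², log-sd 0.8 — a realistic right-skewed distribution on the
cells/mm² scale), exponential survival with either a log-linear hazard in
density/300 or a step at a chosen density, independent uniform censoring
(~12-year horizon tuned to give roughly 40 % events), manual scores
coupled to density with reader noise and two-block averaging with missing
second blocks, and independent clinical covariates. Covariates do not
affect the simulated hazard, so unadjusted biomarker fits are unbiased by
construction; the simulator tests parameter recovery, not confounding.

## Problem sizes and runtime

Tests run single-threaded in a few minutes total: oracle comparisons use
≤ 128×128 rasters and ≤ 50 subjects, end-to-end slides are 3.2–4 mm at
2–4 µm/px, and statistical recovery uses 100 replicates at n = 2000
(Cox) and n = 400 (cutpoint). These sizes were chosen so the whole suite
stays fast while every property is measured at a scale where its
expected behaviour is unambiguous.

## Known limitations

* No real-stain inference ships: the reference backends key on renderer
  colors. They exist to make the pipeline contract executable and
  testable, not to segment H&E.
* Single-resolution processing; no pyramidal WSI decoding or tiling.
* The invasive margin and central stroma are pooled into one density, as
  in the published method — cases with high margin infiltration but an
  empty tumor core average out, a known failure mode of the pooled score.
* The maxstat adjusted p-value is an upper bound; for small candidate
  sets or very small samples, prefer the permutation p.
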