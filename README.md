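# stilquant

Automated quantification of stromal tumor-infiltrating lymphocytes (sTILs)
from class-labeled H&E histology rasters, with survival-based evaluation of
the resulting density biomarker.

## The problem

In triple-negative breast cancer, the density of mononuclear immune cells
in the stroma associated with the invasive tumor is a reproducible
prognostic biomarker, but manual scoring under the TIL Working Group
guideline is laborious and reader-dependent. `stilquant` implements the
downstream, fully deterministic half of an automated scoring pipeline: it
starts from the outputs that tissue- and cell-level classifiers produce
(a class-labeled tissue raster and a list of cell detections) and carries
them through guideline-compliant scoring:

1. **Macro-tumor outline** — local accumulated tumor area under a circular
   kernel (radius 750 µm) is thresholded and smoothed with morphological
   closing/opening, approximating the outline a pathologist would draw
   around the whole tumor.
2. **Tumor-associated stroma** — stroma inside the macro outline plus a
   250 µm invasive margin, excluding tumor, necrosis, and non-invasive
   epithelium.
3. **TIL exclusion** — detected TILs inside tumor or necrosis, or within
   150 µm of non-invasive epithelium (DCIS/LCIS, which attract dense
   lymphoid aggregates), are excluded; every cell receives one audit code.
4. **Density** — sTIL density = kept TILs / stroma area, in cells/mm²,
   plus a local-density heatmap (200 µm kernel) for pathologist review.
5. **Biomarker evaluation** — Kaplan–Meier curves, log-rank tests, Cox
   proportional-hazards models (HRs reported per +10 % manual score or
   +300 cells/mm² density), cutpoint selection by maximally selected rank
   statistics, and concordance against manual scores.

The classifier stages themselves (CNNs in the original work) are
represented by a pluggable backend contract. Shipped reference backends
invert the package's own synthetic slide renderer, so the full pipeline is
exercisable — and testable against exact ground truth — without trained
models or patient data.

## The statistics at the core

For a biomarker *X* and candidate cutpoint *µ*, the two-sample log-rank
statistic over the split {X ≥ µ} vs {X < µ} is standardized as
*z(µ) = (O₂ − E₂)/√V* with hypergeometric variance *V*. The selected
cutpoint maximizes |z(µ)| over all candidates between the 10 % and 90 %
biomarker quantiles; because the maximum of many correlated tests inflates
the naive p-value, the adjusted p uses an improved Bonferroni-type bound
driven by the correlations of neighbouring splits (an exact permutation
p-value is available behind a flag). Cox models use Efron tie handling;
manual scores are dichotomized at "> 10 %", densities at "≥ cutpoint".

## Worked example

```r
library(stilquant)

# a synthetic 4 x 4 mm slide at 2 um/px with known ground truth
sl  <- render_slide(slide_spec(seed = 42))
res <- run_slide(pipeline_config(), labels = sl$labels, cells = sl$cells)
res$result
#> <sTIL biomarker> 370.8 cells/mm^2 (2033 TILs in 5.482 mm^2 stroma)
attr(res$kept, "counts")
#>   KEPT  IN_TUMOR  IN_NECROSIS  NEAR_EPI  OUTSIDE_STROMA  NOT_TIL
#>   2033       569           94       328             297      640
```

Every generated cell is audited exactly once: 569 TILs fell inside tumor,
94 in necrosis, 328 within 150 µm of a DCIS blob, and 297 in stroma
outside the macro-tumor + margin; the 2033 kept TILs over 5.482 mm² of
tumor-associated stroma give the density. On the survival side:

```r
coh <- simulate_cohort(cohort_spec(n = 400, model = "step",
                                   step_location = 470,
                                   step_log_hr = log(0.45), seed = 11))
maxstat_cutpoint(coh$os_time, coh$os_event, coh$stil_density)
#> <maxstat cutpoint> 442.928 (|z| = 5.924, adjusted p = 2.778e-07 [lausen, approximate upper bound])

tidy(cox_fit(coh, "os_time", "os_event", "stil_density"))
#> # A tibble: 1 x 7
#>   term         estimate    HR std_error conf_low conf_high    p_value
#> 1 stil_density   -0.428 0.652    0.0913    0.545     0.779 0.00000269
```

The cutpoint scan recovers the generating step location (470 cells/mm²)
to within the biomarker's resolution, and the Cox HR is reported per
+300 cells/mm². `autoplot()` works on Kaplan–Meier fits and cutpoint
objects; `plot_km_groups()` and `plot_heatmap()` draw the standard
figures.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/stilquant.R simulate slide  --seed 3 --out sim/
Rscript inst/cli/stilquant.R slide  --labels sim/labels.png --cells sim/cells.csv --out out/
Rscript inst/cli/stilquant.R cohort --table cohort.csv --out out/
```

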