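# contuvol

Pulmonary contusion volumetry and outcome statistics from chest CT.

## What it is for

After blunt chest trauma, the share of lung volume occupied by contusion on
the admission CT predicts delayed respiratory complications (pneumonia,
ARDS) better than anatomic injury scores. `contuvol` is aimed at trauma
imaging researchers who want that quantity — and the statistics built on
it — as reproducible code:

- **Segmentation.** Hounsfield-unit pipeline on HU-calibrated CT: a
  rule-based total-lung surrogate (threshold at −250 HU, exterior-air
  removal, component selection, morphological closing + 3D hole filling),
  functionally *normal* lung as the HU window **[−950, −450]**, and
  pneumothorax detection with a 3D mean filter (homogeneous pleural air
  survives smoothing below −950 HU; heterogeneous alveolar air does not).
  Externally produced total-lung masks (e.g. from a learned model) are
  accepted verbatim.
- **Volumetry.** The contusion ratio
  `100 · V_contusion / V_total_lung` (%), the **moderate (≤ 20%) /
  severe (> 20%)** severity classes, P/F ratio and the
  ARDS rule (P/F ≤ 200 + bilateral infiltration + no CHF). Pleural air is
  counted with the normal lung by default (it re-expands after
  thoracostomy); the alternative bookkeeping is a switch, and both are
  always logged.
- **Statistics.** Welch t (summary-statistic or raw form), Mann–Whitney U
  (exact permutation distribution up to n = 30, ties included), Pearson
  chi-square and minimum-likelihood Fisher exact for 2×2 tables, empirical
  ROC/AUC with Youden-optimal thresholds, binormal AUC
  `Φ((m₁−m₂)/√(s₁²+s₂²))`, and age adjustment by pooled-OLS residuals.
- **Synthetic data.** A thoracic CT phantom generator with exact
  ground-truth label maps, and a cohort simulator calibrated to published
  group summaries — so the whole pipeline is testable without patient
  data.
- **I/O.** Self-contained NIfTI-1 read/write and a minimal DICOM CT series
  reader (uncompressed little-endian); no external imaging dependencies.

## Worked example

```r
library(contuvol)

# a 25%-contusion phantom with a 5% pleural air cap, then the full pipeline
ph   <- generate_phantom(phantom_config(target_contusion_fraction = 25,
                                        pneumothorax_fraction = 5, seed = 3))
part <- segment_ct(ph$ct)
contusion_ratio(part)
#> volume_report: total 1129.3 mL, contusion 265.2 mL, pneumothorax 57.6 mL (counted as normal)
#>   contusion ratio 23.48% -> severe (cutoff: >20% is severe)
```

The phantom's true contusion fraction is 25.00%; the segmentation estimate
(23.48%) is within the ±3 percentage points the pipeline is tested to. The
57.6 mL air cap is detected but — under the default bookkeeping — excluded
from the contusion volume while staying inside the total.

```r
# a synthetic 73-patient cohort and the outcome statistics
tab <- simulate_cohort(cohort_config(n = 73, seed = 7))
r   <- cohort_analyze(tab)
r$roc$auc                                  # 0.856  (empirical AUC, this draw)
r$pneumonia_groups$contusion_ratio$welch
#> Welch t (summary): statistic 5.761, df 37.05, two-sided p 1.317e-06

# summary-level checks straight from published group parameters
welch_t_summary(summary_stat(33.04, 11.4, 28), summary_stat(18.3, 8.5, 45))
#> Welch t (summary): statistic 5.897, df 45.56, two-sided p 4.255e-07
round(binormal_auc(summary_stat(33.04, 11.4, 28), summary_stat(18.3, 8.5, 45)), 2)
#> [1] 0.85
```

The pneumonia and non-pneumonia groups differ strongly in contusion ratio
(p < 0.0001), and the binormal AUC from the group summaries is 0.85 — the
discrimination the simulated cohorts reproduce empirically.

A command-line interface covers every stage
(`phantom`, `segment`, `quantify`, `cohort-simulate`, `cohort-analyze`,
`report`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli/contuvol", package = "contuvol"))')
Rscript "$CLI" phantom --out run1 --fraction 25 --ptx 5 --seed 3
Rscript "$CLI" segment --ct run1/ct.nii.gz --out run1/seg
Rscript "$CLI" report --run-dir run1/seg
```

## Layout

- `R/`, `src/` — implementation (S3 containers; Rcpp for the 3D image
  primitives)
- `tests/testthat/` — unit, property and acceptance suites (fixtures are
  generated in code)
- `vignettes/contusion-volumetry.Rmd` — model, parameters, design
  decisions and limitations
- `scripts/acceptance.R` — the acceptance report above
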