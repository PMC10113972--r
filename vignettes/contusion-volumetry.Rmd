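---
title: "Quantifying pulmonary contusion on chest CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pulmonary contusion on chest CT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contuvol)
```

## The problem

Pulmonary contusion — traumatic alveolar hemorrhage and edema — is a major
risk factor for pneumonia and ARDS after blunt chest trauma. Anatomic
scores (chest AIS, ISS) grade what is broken, not how much lung has stopped
participating in gas exchange. A physiologically better severity measure is
the fraction of lung volume occupied by contusion on the admission CT:

\[
\text{contusion ratio} = 100 \times \frac{V_{\text{contusion}}}{V_{\text{total lung}}}\ (\%),
\qquad
\text{severity} =
\begin{cases}
\text{moderate} & \text{ratio} \le 20\%\\
\text{severe} & \text{ratio} > 20\%
\end{cases}
\]

The 20% cutoff reflects the empirically sharp rise in respiratory
complications above that burden. `contuvol` implements the full chain: CT
I/O, lung-field segmentation, pneumothorax detection, volumetry and severity
classification, plus the cohort statistics used to relate the ratio to
outcomes, and synthetic generators (CT phantom, patient table) that make
every step testable without patient data.

## Segmentation model

All intensities are Hounsfield units. Three HU regimes drive the pipeline:

| tissue | HU regime | role |
|---|---|---|
| pure air (pneumothorax, trachea) | $\le -950$ | below the normal window |
| aerated (functional) lung | $[-950, -450]$ | the *normal* window, inclusive at both ends |
| ground-glass / consolidated contusion | $> -450$ | the complement within the lung |

**Total lung.** The reference pipeline used a learned segmentation plus
manual editing; re-implementing a neural model is out of scope, so the
total lung field is obtained by a rule-based surrogate: voxels at or below
`total_lung_hu_max` (default $-250$ HU) are candidates; exterior air is
removed as the candidate components touching the lateral (x/y) volume
borders; components at least 20% the size of the largest are kept (two
lungs, or one if fused; the trachea drops out); morphological closing
(ball, default 5 mm) followed by 3D hole filling pulls ground-glass pores
and consolidation cores interior to the lung back into the mask. An
externally produced total-lung mask (e.g. from a learned model) is accepted
verbatim via `segment_ct(..., total_mask = )` or the CLI flag
`--total-mask`, mirroring how a learned segmentation would be treated as
given.

**Normal lung.** Within the total mask, voxels with HU in $[-950, -450]$
(both bounds included — the boundary convention is tested explicitly),
minus connected components smaller than `min_component_ml` (default 1 mL).

**Pneumothorax.** Pleural air and alveolar air overlap in raw HU, so a
plain threshold cannot separate them. The detector smooths the volume with
a cubic mean filter (default edge 5 voxels): homogeneous pleural air stays
near $-1000$ HU after averaging, while aerated parenchyma — a
tissue/air mixture fluctuating around $-750$ HU — is pulled above the
$-950$ HU air threshold. One refinement over a literal
"threshold-the-filtered-volume" rule: the filtered threshold only *seeds*
the detection, and each detected pocket is delineated as the raw-air
($\mathrm{HU} \le -950$) connected component containing a seed. Without
this, the kernel erodes every pocket by roughly its half-width
(about 3 mm in-plane here), which would bias small-pocket volumes far
beyond the ±10% the detector is expected to deliver on a 30 mL crescent.
Components reaching the superior/inferior volume faces are excluded as
trachea/exterior air, and sub-`min_component_ml` components are dropped. A
degenerate kernel of 1 (no smoothing) is allowed but warned about: the test
suite demonstrates that it false-positives on (untruncated) alveolar noise,
which is exactly why the default kernel is 5.

**Partition.** `derive_partition()` enforces `normal` and `pneumothorax`
inside `total`, gives pneumothorax precedence over the normal window, and
defines contusion as the remainder, so the three classes are pairwise
disjoint and union to the total by construction (asserted voxel-wise).

### Pneumothorax bookkeeping

The source methodology is internally contradictory about whether pleural
air counts with the normal lung (its segmentation section, with the
rationale that a collapsed lung re-expands after thoracostomy) or with the
contusion volume (its ratio-calculation section). The package defaults to
the *normal* assignment and exposes the alternative as
`ptx_counts_as = "contusion"`; every segmentation log records the ratio
under **both** assignments, so the choice is never silent. Under the
default, adding a pleural air pocket leaves the ratio unchanged; under the
alternative it raises the ratio by exactly $100 \cdot V_{ptx}/V_{total}$
(both facts are acceptance-tested).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `normal_hu_window` | $(-950, -450)$ | HU | the stated window for functionally normal lung |
| `air_hu_max` | $-950$ | HU | pure-air bound; the window's lower edge |
| `smoothing_kernel` | 5 | voxels | smallest odd kernel that reliably suppresses alveolar heterogeneity at typical CT noise |
| `min_component_ml` | 1 | mL | sub-mL air pockets are noise at CT resolution |
| `closing_radius_mm` | 5 | mm | seals ground-glass porosity without bridging the mediastinum (lungs are kept > 10 mm apart) |
| `total_lung_hu_max` | $-250$ | HU | admits aerated lung and most ground-glass while excluding soft tissue |
| severity cutoff | 20 | % | fixed by the clinical definition; the boundary value is *moderate* |

The 20% cutoff is applied to raw (unrounded) ratios; whether the original
analysis rounded first is unstated. The simulated patient table stores
ratios at 2 decimal places and derives severity from the stored value, so
the table is always internally consistent.

## The phantom: a stated world

`generate_phantom()` builds a thoracic phantom on a default
$96 \times 128 \times 128$ grid at $2.5 \times 1.5 \times 1.5$ mm spacing:
a soft-tissue thorax ellipsoid, two lung ellipsoids (~575 mL each) of
aerated parenchyma, contusion accreted from random posterior-biased
ellipsoidal blobs (10–28 mm semi-axes) until the target fraction is met
(the last blob is trimmed rim-inward, so achieved fractions match targets
to well under a percentage point), an anterior pleural air cap standing in
for pneumothorax, and an optional pure-air trachea column reaching the top
face (to exercise airway exclusion).

Tissue HU values are drawn from truncated normals: aerated lung
$N(-750, 60)$ truncated to $(-949, -451)$, ground-glass $N(-300, 80)$ on
$(-449, -100)$, consolidation $N(20, 30)$, pleural/airway air near
$-1000$ HU truncated to $\le -951$, soft tissue $N(40, 10)$. Only the
normal-lung window is externally specified; the other means are
conventional radiology values, configurable via `default_hu_model()`, and
the tests only rely on each tissue falling on the correct side of the
$-950$/$-450$ thresholds. Truncation prevents HU leakage across class
boundaries, which is what makes the truth masks unambiguous — and it also
means the default phantom is *cleaner* than real data: a green phantom test
establishes algorithmic correctness under the stated HU regimes, not
robustness to scanner noise, partial-volume mixing, motion, or breathing
phase (the latter is an acknowledged limitation of admission-CT volumetry
in general). The degenerate-kernel test deliberately lifts the aerated
truncation to restore the realistic $N(-750,60)$ tail below $-950$ HU.

What the phantom does **not** model: airways beyond the trachea, vessels,
ribs, effusions, respiratory motion, contrast-phase effects. No
compensation for contrast-enhanced HU shifts is implemented.

## The synthetic cohort: a stated world

`simulate_cohort()` draws pneumonia status first (prevalence 28/73), then
contusion ratio, GCS, ISS and lactate from pneumonia-conditional truncated
normals with the published (mean, SD) pairs; severity follows from the
ratio; age is drawn conditional on severity; ARDS (5/38) and mortality
(2/38) occur only in the severe stratum, which exercises the
zero-cell/Fisher code path. Covariates are independent given pneumonia
status: only marginal group summaries are published, so independence is the
minimal assumption, and it is why the simulated severity split is checked
against a numeric mixture-tail oracle rather than the published 35/38
split (which also carries sampling noise and real-data dependence).

Configured means are *pre-truncation* parameters. The induced bias is
quantified in the tests by numerical integration: negligible for the
pneumonia-group ratio (lower bound 2.9 SD below the mean), about +0.34
percentage points for the non-pneumonia group. The published text and table
disagree on the non-pneumonia SD (8.4 vs 8.5); the table value 8.5 is the
default and the field is configurable.

## Statistics

* **Welch t** (default) from summary statistics or raw data; the raw-data
  route computes summaries and delegates, so the two agree exactly. The
  source says only "t test"; Welch is the default because it reproduces the
  published p-values from the published summaries better than the pooled
  form, which remains available (`pooled = TRUE`).
* **Mann-Whitney U**: exact permutation distribution (DP over pooled
  midranks, valid under ties) for $n_x + n_y \le 30$, two-sided as
  $\min(1, 2\min(P_{\le}, P_{\ge}))$; tie- and continuity-corrected normal
  approximation otherwise.
* **2×2 tables**: Pearson chi-square (optional Yates) and Fisher exact
  with the minimum-likelihood two-sided convention — the most common
  software default; the original convention is unrecoverable. The analysis
  report computes both and recommends chi-square only when all expected
  cells are at least 5. Notably, the published ARDS (0.090) and mortality
  (0.54) p-values are not reproduced by Pearson, Yates, or minlike Fisher
  from the printed counts (minlike Fisher gives 0.055 and 0.494); this is
  flagged rather than chased.
* **ROC**: empirical curve over all distinct thresholds; AUC by the
  Mann-Whitney identity with ties credited one half (provably equal to the
  trapezoidal area of the stored curve); Youden-optimal threshold with
  ties broken toward higher sensitivity. Scores that run opposite to risk
  (normal-lung percentage) are handled by `higher_is_positive = FALSE`
  with thresholds reported on the caller's scale. A percentile bootstrap
  CI for the AUC is provided but not validated against the published CI,
  whose method is unstated.
* **Binormal AUC** $\Phi\!\big((m_1 - m_2)/\sqrt{s_1^2 + s_2^2}\big)$ for
  summary-level validation of discrimination claims.
* **Age adjustment**: pooled OLS of score on age, residuals summarized per
  group (mean ± SD) and compared by Welch t — the residualization route
  described for the published age adjustment. Which variable was
  residualized is ambiguous in the source, so the function takes the score
  as an argument rather than guessing.
* No multiple-testing correction is applied anywhere, matching the source;
  reports carry a note to that effect.

## Numerical and degenerate-input choices

* Box filter borders use truncated windows (mean over in-volume voxels).
* Connected components use 6-connectivity; labels are assigned in linear
  scan order, so all component operations are deterministic.
* "Two largest components" ties (fused lungs) resolve by size then label
  order.
* Ratio of an empty total lung is an error, not NaN; degenerate 2×2
  margins are an error for chi-square and p = 1 for Fisher; single-class
  ROC labels are an error.
* FiO2 above 1.5 is auto-interpreted as a percentage (divided by 100, with
  a message); the P/F = 200 boundary counts as ARDS-qualifying.
* All masks serialize as unsigned 8-bit NIfTI; HU volumes as 32-bit float
  (round trips are exact for masks, float32-rounded for HU).
* NIfTI and DICOM support is a deliberately minimal, self-contained subset
  (single-file NIfTI-1; uncompressed little-endian CT DICOM without
  sequences); anything outside it raises a typed error instead of guessing.

## Known limitations

* The total-lung surrogate is not a learned model: on real CT with dense
  peripheral consolidation abutting the pleura it will under-close, which
  is why external masks are accepted. On the phantom it recovers truth
  with Dice ≥ 0.95 (no contusion) and ≥ 0.90 (40% contusion including
  consolidation) — those figures are computed by the test suite, not
  claimed beyond it.
* Severity has exactly two classes; there is no mild class and no
  Berlin-style ARDS grading.
* The cohort simulator models marginals, not joint structure; it cannot
  reproduce per-patient results such as the published optimal threshold
  (70.4% of normal lung), which depend on the unavailable raw cohort.
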