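# contourdose

Geometric accuracy metrics for radiotherapy organ-at-risk segmentations are
only useful if they track the error that matters clinically: the difference
in reported dose. `contourdose` implements the analysis that connects the
two for parallel organs (parotid-like and larynx-like dose geometries),
aimed at medical-physics and auto-segmentation researchers who need to
decide which geometric metric is an acceptable surrogate for dosimetric
accuracy.

The package provides:

* a voxel-structure data model on physical grids (voxel-center convention),
  with planar-contour rasterization (even-odd rule), face-center surface
  extraction, and NIfTI I/O;
* the six standard comparison metrics for a structure pair `(auto, ref)`:

  | metric | definition |
  |---|---|
  | DSC | `2·(V1 ∩ V2) / (\|V1\| + \|V2\|)` |
  | CI | `V(auto) / V(ref)` |
  | centroid separation | `‖c(auto) − c(ref)‖` (mm) |
  | meanDTA / maxDTA | mean / max of the directed DTA histogram (ref → auto) |
  | 95%-HD | 95th percentile of the cumulative DTA histogram |

  where the distance-to-agreement (DTA) of a reference-surface point is its
  shortest distance to any point of the target surface;
* STAPLE expectation–maximization fusion of multiple observer contours into
  a probabilistic ground truth (per-rater sensitivity `p_j` and specificity
  `q_j`, scalar prior, ROI-restricted), with a thresholded binary consensus;
* dosimetry: trilinear dose sampling, mean structure dose, the signed
  dosimetric accuracy `100·(D̄_auto − D̄_ref)/D̄_ref` (%), and the per-case
  dosimetric interobserver variation (each observer vs the fused reference)
  with an outside-range flag;
* a Pearson correlation study pooling cases per organ group
  (two-sided p, significance at p < 0.05);
* a seeded synthetic cohort generator — smooth organ phantoms, observer and
  auto-contour error models, and dose fields in two regimes: a steep
  unidirectional gradient (parotid-like) and opposing gradients with a
  central trough (larynx-like).

See `vignettes/geometric-dosimetric-accuracy.Rmd` for the model, parameter
and tie-break documentation.

## Worked example

```r
library(contourdose)

# one synthetic parotid-like case: truth, 5 observers, auto contour, dose
cohort <- generate_cohort(3, "parotid-like", seed = 42)
case <- cohort$cases[[1]]

rec <- build_case_record(truth = case$truth, raters = case$raters,
                         auto = case$auto, dose = case$dose,
                         case_id = case$case_id)
rec
#> case_record parotid_001 (organ): DSC 0.781, centroid 5.15 mm, accuracy -20.53%, OUTSIDE IOV
rec$iov
#> iov: min -13.70% | Q1 -2.98% | median -1.89% | Q3 +13.29% | max +13.87%
```

The record says: against the STAPLE consensus of the five observers, the
auto contour — displaced 5 mm down-gradient — reports a mean dose 20.5 %
lower than the reference. The five observers themselves disagree by
−13.7…+13.9 % on this steep-gradient case, and the auto contour still falls
outside that band, so its dose estimate is worse than observer disagreement
can explain.

The full study is the numbered workflow in `analysis/`:

```sh
Rscript analysis/01_simulate_cohorts.R   # 20 parotid-like + 10 larynx-like cases
Rscript analysis/02_case_analysis.R      # STAPLE + metrics + dosimetry per case
Rscript analysis/03_correlation_study.R  # pooled correlations, counts, summary
Rscript analysis/04_figures.R            # IOV box plots, scatter plots
```

Step 3 prints, per organ group, the correlation of each metric with
dosimetric accuracy, e.g.:

```
  parotid-like  centroid_sep_mm  r = -0.74  p = 0.0002 *
  parotid-like  dsc              r = +0.70  p = 0.0006 *
  larynx-like   centroid_sep_mm  r = +0.06  p = 0.8657
  larynx-like   mean_dta_mm      r = -0.54  p = 0.1035
```

showing the regime dependence: on a unidirectional gradient the centroid
separation is the strongest correlate of dose error, while in the
opposing-gradient trough the organ's position is dosimetrically almost
irrelevant and only surface/boundary metrics carry signal. Tables land in
`results/` (`case_records.csv`, `correlation_table.csv`, `summary.json`).

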