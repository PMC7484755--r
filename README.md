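# t2quant

Quantitative analysis of probe-enhanced multi-echo T2-weighted MRI for
monitoring tumor response to chemotherapy — with a fully synthetic,
ground-truthed test bed.

## The problem

Iron-oxide nanoparticle probes targeted at tumor antigens (e.g. the
uMUC1-binding MN-EPPT conjugate) shorten the transverse relaxation time T2
where they accumulate, darkening the lesion on T2-weighted images
(negative contrast). Since antigen expression drops when a tumor responds
to chemotherapy, the decrease in mean tumor T2 after probe injection,

```
deltaT2 = mean ROI T2 (pre-injection) − mean ROI T2 (post-injection),
```

quantifies probe binding and hence therapy response. `t2quant` implements
the full analysis chain used in such studies:

* **T2 relaxometry** — per-voxel fit of `y = A·exp(−t/T2)` to multi-echo
  signals (log-linear initialization, vectorized Levenberg–Marquardt
  refinement, validity flags).
* **Tumor segmentation** — a compact slice-wise encoder–decoder with skip
  connections trained on soft dice loss
  (`1 − (2Σpg + s)/(Σp + Σg + s)`) with SGD at lr 4e-3, batch 8, weight
  decay 1e-7; plus a deterministic Otsu-with-bimodality-gate reference
  segmenter.
* **ROI geometry** — Feret (longest caliper) diameter on the pixel-corner
  convention, circularity `4π·area/perimeter²`, roundness
  `4·area/(π·major_axis²)`, pixel sums and mean ROI intensity.
* **Response analysis** — deltaT2 and RECIST classification (CR on lesion
  dissolution; PD on ≥ 20 % diameter increase or new lesions; PR on
  ≥ 30 % decrease; SD otherwise — thresholds inclusive).
* **Inter-rater validation** — two-way mixed, absolute-agreement ICC with
  F test and 95 % CI, `ICC(A,k) = k·r/(1+(k−1)·r)` of `ICC(A,1)`.
* **CTCF** — corrected total cell fluorescence,
  `IntDen − area × mean(background)`.
* **Synthetic phantoms** — multi-echo stacks with an ellipsoidal lesion,
  known T2 fields, exact masks/diameters/deltaT2, seeded and pure.

See `vignettes/t2quant-methods.Rmd` for the models, parameter choices and
limitations.

## Worked example

```r
library(t2quant)

# a tumor phantom: 15 slices, tumor T2 60 ms pre-injection on an 80 ms
# background; the probe shortens tumor T2 to 40 ms post-injection
spec <- phantom_spec(grid_shape = c(15, 32, 32), tumor_center = c(8, 16, 16),
                     tumor_radii = c(3, 6, 6), noise_sigma = 2, seed = 42)
pair <- generate_longitudinal_pair(spec, t2_tumor_post = 40)
pair$truth$true_delta_t2
#> [1] 20

map_pre  <- reconstruct_t2_map(pair$pre)
map_post <- reconstruct_t2_map(pair$post)
roi_pre  <- oracle_segment(map_pre,  "lower")   # lesion is hypointense
roi_post <- oracle_segment(map_post, "lower")

d <- delta_t2(map_pre, roi_pre, map_post, roi_post)
c(pre = d$mean_roi_pre, post = d$mean_roi_post, delta = d$delta_t2)
#>      pre     post    delta
#> 59.98475 40.02707 19.95768

# diameter-based response call: a lesion that grew 10.2 -> 12.4 mm
recist_classify(10.2, 12.4)$category
#> [1] "PD"

# inter-rater agreement, two-way mixed / absolute agreement
rt <- generate_rater_table(38, 2, var_subject = 1, var_rater = 0.02,
                           var_error = 0.08, seed = 1)
r <- icc_absolute_agreement(rt)
round(c(single = r$icc_single, average = r$icc_average), 3)
#>  single average
#>   0.924   0.960
```

The recovered `delta` sits within 0.2 % of the simulated 20 ms ground
truth; the ICC example mirrors the single/average-measures structure of a
published agreement table (`spearman_brown(r$icc_single, 2)` reproduces
the average-measures row exactly).

`run_pipeline(pipeline_config(seed = 1))` chains the whole analysis for a
simulated two-arm cohort (treated tumors get a smaller probe-induced T2
drop and grow less) and returns one record per subject: ROI means,
deltaT2, diameters and the RECIST category, plus a treated-vs-control t
test on deltaT2.

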