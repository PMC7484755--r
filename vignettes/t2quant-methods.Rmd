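---
title: "Quantitative T2 analysis of tumor response: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative T2 analysis of tumor response: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2quant)
```

# The problem

Iron-oxide nanoparticle probes targeted at tumor antigens (such as the
uMUC1-binding MN-EPPT conjugate) act as negative MR contrast agents: where
the probe accumulates, the transverse relaxation time T2 shortens and the
tissue darkens on T2-weighted images. Because antigen expression falls when
a tumor responds to chemotherapy, the *drop in tumor T2 after probe
injection* — the **deltaT2** statistic — is a quantitative readout of probe
binding, and therefore of antigen expression and therapy response.
`t2quant` implements the complete analysis chain for such studies:

1. voxelwise T2-map reconstruction from multi-echo acquisitions,
2. automated tumor ROI segmentation (a trainable encoder–decoder and a
   deterministic threshold-based reference segmenter),
3. ROI descriptors (Feret diameter, circularity, roundness, pixel sum,
   mean intensity),
4. deltaT2 and RECIST response classification,
5. inter-rater validation by two-way mixed absolute-agreement ICC,
6. corrected total cell fluorescence (CTCF) for the companion microscopy.

Every stage is exercised on synthetic phantoms with analytic ground truth,
so the whole pipeline is testable without any acquired data.

# Signal model and T2 fitting

Each voxel's multi-echo magnitude signal is modeled as a mono-exponential
decay

$$y(t) = A\, e^{-t/T_2},$$

with amplitude $A$ (signal units) and relaxation time $T_2$ (ms). There is
deliberately no baseline/offset term: the model is fit exactly as printed.
`fit_voxel_decay()` minimizes the untransformed least-squares objective
$\sum_i (y_i - A e^{-t_i/T_2})^2$. A log-linear regression of $\log y$ on
$t$ supplies the starting point only; it is not used as the estimate,
because log-domain noise is skewed and would bias $T_2$. Refinement uses a
Levenberg–Marquardt iteration whose $2 \times 2$ damped normal equations
are solved in closed form, vectorized across all voxels of a stack
(`reconstruct_t2_map()` fits a 15×64×64×8 stack in a few seconds).

Numerical choices:

* **Bounds** `t2_min = 1`, `t2_max = 2000` ms. A fit that pins to a bound
  (e.g. a non-decaying signal, whose $T_2 \to \infty$) is flagged invalid.
* **Flooring**: signals are floored at a machine-epsilon multiple of the
  stack maximum before the log initialization; any voxel with a
  non-positive raw signal is flagged invalid rather than silently floored.
* **Validity propagation**: invalid voxels carry `NA` and are excluded
  from every downstream ROI statistic.
* **Convergence**: relative step below `1e-11`; noiseless phantoms are
  recovered to better than `1e-8` relative error (asserted in the tests).

# Synthetic phantoms

`phantom_spec()` / `generate_phantom()` simulate the acquisition forward
model on a uniform background with one axis-aligned ellipsoidal lesion.
Defaults (all configurable):

| parameter | default | rationale |
|---|---|---|
| stack | 15 slices, 64×64 | the per-map slice count of the study design, at desk scale in-plane |
| echo grid | 8 echoes, 8–120 ms | brackets both tumor (40–60 ms) and background (~80 ms) T2; the source protocol's echo times are not stated |
| background T2 | 80 ms | typical tumor-adjacent soft tissue at high field |
| tumor T2 pre/post | 60 / 45 ms | a strong probe-induced shortening; the dose-to-deltaT2 mapping is not published, so these are stated defaults, not calibrated values |
| noise | gaussian, sigma 2 (SNR ≈ 50 at the first echo) | magnitude-MRI noise is Rician but near-gaussian at this SNR; a `rician` option exists |

The generators are pure functions of their spec (seed included), asserted
bit-for-bit in the tests. Ground truth carries the exact T2 field, tumor
mask, per-slice Feret diameter (computed by brute force, independently of
the metrics module it validates), and — for longitudinal pairs — the exact
`true_delta_t2`.

What the phantoms deliberately do **not** emulate: irregular lesion
shapes (the ellipsoid keeps ground-truth geometry analytic), partial-volume
edges, B1/B0 inhomogeneity, motion, and multi-lesion anatomy. Passing
tests demonstrate the correctness of the estimators and the pipeline
plumbing, not performance on clinical data.

# Segmentation

## Trainable network

`train_model()` fits a compact 3-level encoder–decoder with skip
connections, applied to each slice independently (the study describes
per-slice sequential evaluation of a 15-channel stack; whether any state is
shared across slices is unspecified there, so slice independence is chosen
and documented). Blocks are conv(3×3) → instance norm → ReLU, twice per
level, with 2×2 max pooling, nearest-neighbor upsampling, and a 1×1 sigmoid
head that additionally sees the raw standardized input as a skip channel.
The whole network — forward, backward, SGD — is implemented natively in R
on BLAS matrix operations; backpropagation is verified against central
finite differences in the test suite.

Training minimizes the **soft dice loss**

$$L = 1 - \frac{2\sum_i p_i g_i + s}{\sum_i p_i + \sum_i g_i + s},
\qquad s = 1,$$

by stochastic gradient descent with the study's hyperparameters —
learning rate `4e-3`, batch size `8`, weight decay `1e-7` — plus classical
momentum (default `0.95`) and default `100` epochs. The smoothing constant
keeps empty-vs-empty slices at loss 0 instead of 0/0.

Design notes a maintainer should know:

* **Instance normalization** is the conditioning that makes the small
  fixed learning rate productive on the dice objective; without a
  normalization layer the gradient scale at `lr = 4e-3` is orders of
  magnitude too small to converge in any realistic epoch budget, and with
  plain dice loss the empty-background gradient can drive the logits into
  saturation.
* The **training corpus** (`generate_training_corpus()`) emulates a
  radiologist-curated ground-truth set: predominantly tumor-bearing
  slices from phantoms with varied lesion geometry, tumor T2 (40–60 ms)
  and background T2 (75–85 ms), plus roughly one lesion-free slice in six
  as negative examples. The balance matters in both directions: a corpus
  dominated by empty targets under pure dice loss drives the logits into
  all-background saturation (the empty-slice gradient only ever pushes
  predictions down), while a corpus with no negatives yields a model that
  hallucinates small components on background-only slices because the
  normalization layers make it contrast-invariant.
* The **input intensity skip** into the 1×1 head is load-bearing, not
  decorative: instance normalization makes the feature pathway
  contrast-invariant, so without the skip the network cannot distinguish
  a faint noise dip on a lesion-free slice from a genuine hypointense
  lesion — it hallucinates small components on empty slices no matter how
  long it trains. With the skip, the head gates on absolute T2 level
  (tumor ≈ −2 SD vs noise dips ≈ −0.5 SD) and empty slices go quiet.
  The skip weight is initialized at −1 — hypointense lesions mean lower
  signal should raise the foreground logit — because whether SGD discovers
  that gate from a random start turns out to be seed-dependent; starting
  from the physically expected sign makes the suppression reliable while
  leaving training free to reshape or flip it.
* The output bias is initialized at the logit of the corpus foreground
  prior rather than 0, a standard warm start for heavily imbalanced masks.
* Inference (`predict_mask()`) thresholds the soft output at 0.5 and keeps
  the largest 4-connected component per slice — the single-lesion model of
  this study; multi-lesion anatomy is out of scope for the segmenter.
* At the packaged problem size (48 training slices of 64×64, 16 held-out)
  the trained model reaches mean held-out Dice ≥ 0.85; a typical run sits
  near 0.99. The 48/16 split is the package's desk-scale stand-in for the
  ~600-image corpus of the original study.

## The printed gradient-descent machinery

`mse_cost_and_gradient()` evaluates, verbatim, the mean-squared-error cost
$f(m,b) = \frac1N\sum_i (y_i - (m x_i + b))^2$ and its analytic gradient.
This linear-regression objective is the gradient-descent illustration that
accompanies the training procedure in the source methodology; it is *not*
the segmentation loss (that is the dice loss above). It ships as a
documented, finite-difference-verified utility.

## Deterministic reference segmenter

`oracle_segment()` is a training-free baseline used to test downstream
stages independently of training stochasticity: a per-slice two-class
threshold by between-class-variance maximization (Otsu), keeping the
largest connected component on the expected-contrast side (`"lower"` for
T2-shortened lesions). Two failure modes of plain Otsu shaped the design:

* On a **tumor-free noisy slice**, Otsu happily splits unimodal background
  noise and emits a large spurious component. The remedy is a
  **bimodality gate**: a split is accepted only when the standardized
  between-class separation $(\mu_{hi}-\mu_{lo})/\sigma_{within}$ exceeds
  `min_separation = 3.3`. Splitting a unimodal gaussian gives a
  separation of ≈ 2.65 regardless of scale, while a genuine two-tissue
  slice at this pipeline's contrasts measures ≥ 4.5, so the gate sits in
  a wide empirical gap.
* A **stack-level** threshold (`scope = "volume"`) sounds more robust but
  is not: at the ~3% tumor volume fractions of these phantoms, the
  between-class-variance criterion can prefer splitting the large
  background mode over isolating the small lesion class (the classic
  Otsu class-imbalance failure). Per-slice thresholds see tumor fractions
  of ~10% on lesion-bearing slices and are reliable, so `"slice"` is the
  default and the gate handles the lesion-free slices.

# ROI metrics

Conventions match the manual measurement tool used by the raters:

* **Feret diameter** — maximum pairwise distance over the *pixel-corner*
  points of the region (convex hull first, exact). The corner convention
  means a single pixel has diameter $\sqrt 2$; a pixel-center convention
  would give it diameter 0. Verified against an exhaustive pairwise oracle.
* **Circularity** $= 4\pi\,\mathrm{area}/\mathrm{perimeter}^2$, with the
  perimeter measured on the traced pixel-edge boundary polygon after two
  corner-cutting passes (each 90° turn is replaced by a chord of at most
  half a pixel per side, so a unit staircase collapses to its exact
  diagonal). The perimeter estimator is the dominant source of
  circularity differences between implementations: raw crack length would
  give a digital disc circularity ≈ 0.62, one cutting pass ≈ 0.9, two
  passes ≈ 0.94 with the 30×30 square held near $\pi/4$.
* **Roundness** $= 4\,\mathrm{area}/(\pi\,\mathrm{major\_axis}^2)$, major
  axis $4\sqrt{\lambda_{max}}$ from second-order central moments of pixel
  centers with the 1/12 pixel-extent term (the moments-equivalent
  ellipse), so a single pixel is round, not degenerate.
* **Mean ROI intensity** — exact sums over mask ∩ valid voxels.
* The per-map "longest diameter" for response classification is the
  maximum per-slice Feret over the stack (`longest_diameter()`); the
  analysis is strictly 2-D, matching the coronal single-plane design —
  no 3-D Feret or volume estimation.

# deltaT2 and response classification

`average_t2()` pools the mean over slices with pixel-count weights
(total intensity sum / total pixel count), which equals the mean over all
tumor voxels and is invariant to re-slicing. The alternative reading of
the pooling description — an unweighted mean of per-slice means — would
weight a 1-pixel edge slice as much as the equatorial slice; the weighted
form is chosen and documented. `delta_t2()` subtracts post-injection from
pre-injection means; pre and post masks are segmented independently
(whether the original analysis reused one mask is unstated).

`recist_classify()` applies the response rules with **inclusive**
thresholds, per their "≥" definitions: CR when the lesion has dissolved
(empty follow-up mask across all slices), else PD when new lesions are
present or the diameter increased ≥ 20%, else PR when it decreased ≥ 30%,
else SD. The documented precedence (CR → PD-new-lesions → PD-diameter →
PR → SD) is exercised by a 0.1%-step boundary sweep in the tests.

# Inter-rater agreement

`icc_absolute_agreement()` implements the two-way mixed-model,
absolute-agreement intraclass correlation from its ANOVA decomposition
(rows = subjects, columns = raters):

$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}
 {MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},
\qquad
\mathrm{ICC}(A,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n},$$

with $F = MS_R/MS_E$ on $(n-1,\,(n-1)(k-1))$ degrees of freedom and the
standard absolute-agreement 95% interval (Satterthwaite denominator df for
the single-measures bound; average-measures bounds through the
single-to-average relation). `spearman_brown()` exposes that relation,
$k r / (1 + (k-1) r)$, which links the single- and average-measures rows
of a published agreement table exactly. The implementation supports any
$k \ge 2$; $k = 2$ is the validated case (the published degrees of freedom
imply two raters). A brute-force sums-of-squares oracle and a consistency-
definition contrast are kept in the test suite, not in the API.

# CTCF

`ctcf()` evaluates, per labeled cell,
$\mathrm{CTCF} = \mathrm{IntDen} - \mathrm{area} \times
\overline{\mathrm{bg}}$. The background region is an explicit mask rather
than a freehand selection, for reproducibility; multi-channel images are
quantified one channel at a time after splitting. CTCF is linear in
intensity and zero for a uniform image, both asserted as properties.

# Pipeline

`run_pipeline()` chains simulate → fit → segment → measure → classify for
a two-arm cohort in which treated tumors receive a smaller probe-induced
T2 drop (52 ms vs 42 ms post-injection against a 60 ms baseline) and lower
follow-up growth factors (0.6–1.1× vs 1.7–2.1×, the controls roughly
doubling over the course). All seeds derive from the config seed; reruns
are byte-identical. The demo grid is 15×32×32 so a 6-subject cohort runs
in under a minute. `make_fixtures()` materializes the seeded corpus
(NIfTI series and maps, PNG masks, CSV tables, a PNG fluorescence panel)
with an MD5 manifest.

# Known limitations

* Mono-exponential T2 only; no multi-component decay, B1 or
  stimulated-echo correction.
* Single lesion per stack; multi-lesion response enters only through the
  `new_lesions` argument of the classifier.
* The phantom noise and contrast regime is idealized; segmentation scores
  on phantoms do not transfer to clinical images.
* The network is intentionally small (tens of thousands of parameters);
  it is the study-shaped method at desk scale, not a production segmenter.
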