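---
title: "Quantifying micropatterned colony assays: models and design choices"
author: "micropattern package authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying micropatterned colony assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The assays and their readouts

Human pluripotent stem cells confined to 500 µm circular micropatterns
self-organize reproducible spatial signalling patterns. Two endpoint assays
are quantified here:

* **Activin A assay.** After a 1 h apical activin A pulse, wild-type
  colonies restrict SMAD2/3 nuclear translocation to a band at the colony
  edge; perturbed lines show patchy interior activation or activation
  throughout. The per-colony readouts are (i) the radial profile of nuclear
  SMAD2/3 intensity versus distance to the colony center, normalized to its
  maximum, (ii) mean nuclear intensity inside a center band (10–25 µm) and
  an edge band (175–225 µm), and (iii) the percentage of SMAD2/3-positive
  nuclei under a binary threshold.
* **Neuruloid assay.** Day-7 neuruloids organize a central PAX6
  neuroectoderm domain containing an N-CAD lumen, surrounded by a SOX10
  neural-crest ring. The readout is each marker's segmented pixel area as a
  fraction of the total DAPI area.

Group differences are assessed by one-way ANOVA followed by Dunnett's
many-to-one comparisons against the control line (or Tukey's all-pairs
test), with the usual star convention (\*: p < 0.05 through \*\*\*\*:
p < 0.0001, ns otherwise). The statistical unit is always the colony,
never the nucleus.

# Processing chain

## Colony detection

The DAPI channel is thresholded with Otsu's criterion on its normalized
intensity range — making detection invariant to any positive rescaling of
the channel — followed by morphological closing with a 5 µm disc and hole
filling. Connected components are filtered by an area window
$[1-\tau,\,1+\tau]\cdot\pi (D/2)^2$ around the expected colony diameter
$D$ (default $\tau = 0.35$), which drops merged pairs, partial colonies and
debris; components touching the image border are rejected with reason
`"border"`. The colony boundary is the convex hull of the component — the
micropatterns are convex discs, so the hull equals any reasonable
alpha-shape of the foreground while needing no scale parameter — and the
colony center is the centroid of that boundary polygon.

## Nucleus segmentation and measurement

Nuclei are segmented from the DAPI channel of a colony crop by Otsu
threshold, hole filling, and marker-controlled watershed on the Euclidean
distance transform, which splits touching nuclei at their waist. The
watershed merge tolerance (default 0.3 px on the distance map) plays the
role of a minimum peak separation: deeper saddles split, shallower merge.
Labels are then filtered to an area window of 30–300 µm² to exclude debris
and mitotic figures, with every removal logged.

Per nucleus we record centroid, area, distance to the colony center, and
both the median and the mean intensity over the nucleus mask in each
measurement channel. Medians use the **lower-median** convention for even
pixel counts so every reported value is attained in the image. The radial
profile uses the median (robust to segmentation spill-over); binary
positivity classification uses the mean; both are always available.

## Radial profiles and band summaries

Nuclei are binned by distance into half-open intervals $[lo, hi)$ of 10 µm
width up to 250 µm; the bin statistic is the mean of per-nucleus medians.
Empty bins carry `NA`, never 0, and nuclei beyond the maximum radius are
tallied in an overflow count and excluded. Normalization divides all bins
by the maximum over non-empty bins, so the normalized maximum is exactly 1
and the operation is idempotent; it is applied per colony when colonies
are compared statistically, and profiles can also be aggregated first and
normalized as a mean profile for display. Band summaries average
per-nucleus intensities directly (not bin means) within the center band
(10–25 µm; the innermost 10 µm are excluded, avoiding the small-n
singularity at the center) and edge band (175–225 µm).

## Positive-nucleus fractions

A nucleus is positive when its intensity is strictly above the threshold;
ties are negative. Rather than a manual threshold, two reproducible
estimators are provided and always recorded with the result: Otsu's
criterion on the pooled control-nucleus intensity histogram (256 bins;
the default), and the midpoint of two k-means cluster centers initialized
at the pooled minimum and maximum (deterministic). One global threshold is
estimated per run from the control condition, mirroring a single manual
setting per experiment batch. If the two cluster centers collapse to
within 5% of the intensity range the distribution is effectively unimodal
and the result is flagged degenerate.

## Neuruloid domain areas

Marker areas are segmented classically: Gaussian smoothing (σ = 2 µm),
Otsu threshold on the smoothed range, morphological opening (3 µm disc),
and removal of components below 100 µm². Fractions are
$|M \cap \mathrm{DAPI}| / |\mathrm{DAPI}|$ by default ("clip" mode,
guaranteeing values in [0, 1]); a "raw" mode without clipping is available
and flagged in the output. The N-CAD lumen is measured as a filled region.

## Group statistics

One-way ANOVA uses the classical fixed-effects decomposition (via
`stats::aov`). Dunnett's two-sided many-to-one adjusted p-value is
$P(\max_j |T_j| \ge |t_{\mathrm{obs}}|)$ under the equicorrelated
multivariate t null with loadings
$\lambda_j = \sqrt{n_j/(n_j+n_0)}$, evaluated by deterministic
Gauss–Legendre double quadrature over the shared control factor and the
pooled-χ factor (96 nodes per dimension; absolute error well below 1e−4,
verified in the test suite against quasi-Monte-Carlo multivariate-t
integration and a 10⁶-draw Monte Carlo of the max statistic). Tukey's
all-pairs p-values come from the studentized range distribution
(`stats::ptukey`, Tukey–Kramer for unbalanced designs). The classical
equal-variance pooled-SD forms are used throughout, matching standard
Prism-style analysis; Welch-type variants are out of scope. Adjusted
p-values always dominate the corresponding unadjusted t-test p-values.

# The synthetic generator

Because the assay readouts are defined on images that are not distributed
with the package, every stage is validated against a generator with known
ground truth.

* **Layout.** Nucleus centers are placed by Poisson-disc sampling
  (Bridson's algorithm plus a random-sequential densification pass) in a
  250 µm disc with a hard minimum separation (default 8 µm), then
  subsampled to the target count (default 1800, a dense epithelium of
  roughly 0.009 nuclei/µm²). The separation guarantee is what makes
  nucleus-count recovery a testable property. Requests beyond the
  hexagonal-packing bound raise an error naming the feasible maximum;
  feasible-but-unreached targets return a flagged shortfall.
* **Nucleus size.** Radii are uniform in 3.5–4.5 µm (7–9 µm nuclei,
  typical of dense pluripotent epithelium). This range was chosen
  deliberately so that the default 8 µm separation implies (near)
  non-overlap: with larger nuclei the layout's own non-overlap guarantee
  and the count-recovery property cannot hold simultaneously, since
  heavily fused nuclei have no watershed-detectable waist.
* **Activation.** Nuclei at distance ≥ colony radius − edge-band width
  (default 50 µm) are activated with probability `pEdge`; interior nuclei
  with probability `pCenter`. Presets: WT (1, 0), HET (1, 0.4 with 40 µm
  patches), HD and KO (1, 1). Patchy interior activation thresholds a
  Gaussian-smoothed white-noise field at the empirical `pCenter` quantile
  of the interior field values: the realized interior fraction equals
  `pCenter` up to rounding while labels cluster at the requested
  correlation length. (A marginal-probability threshold would leave
  patch-level variance of several percentage points even in large
  colonies, making exact fraction-recovery assertions meaningless.)
* **Rendering.** Nuclei are drawn as discs (DAPI at 150 a.u.; SMAD2/3 at
  200 a.u. when activated, 20 a.u. otherwise), Gaussian-blurred with
  σ = 0.8 µm for optical softening, and overlaid with Gaussian background
  (mean 10 a.u. = 5% of the on-level, sd 4 a.u. = 2%) and optional Poisson
  shot noise. Intensities are arbitrary units; absolute calibration is out
  of scope. Default sampling is 1 µm/px (520×520 images for a 500 µm
  pattern plus margin). Identical parameters and seed reproduce images
  bit-exactly.
* **Neuruloids.** Endpoint geometry only: concentric DAPI/PAX6/N-CAD
  discs and a SOX10 annulus with analytic truth fractions ($(r/R)^2$ and
  $(r_2^2-r_1^2)/R^2$). Presets encode the phenotype direction (WT
  110/55/180–240 µm; HD 150/85/205–240 µm; HET intermediate, KO extreme),
  and per-colony log-normal radius jitter (σ = 0.03) provides biological
  variability while preserving nesting. No morphogenesis dynamics are
  simulated.

The generator emulates the geometry and intensity statistics that the
pipeline's readouts depend on. It does **not** emulate uneven
illumination, chromatic aberration, a realistic point-spread function,
out-of-focus light, nuclear texture, or segmentation-adversarial shapes;
passing tests therefore demonstrate correctness of the quantification
chain on idealized-but-noisy inputs, not segmentation robustness on
arbitrary real micrographs.

# Numerical and design choices

* Pixel coordinates are 0-based, origin top-left, x along columns, y along
  rows; micrometers = pixels × pixel size, with pixel centers at half-pixel
  offsets. All modules share this convention.
* Half-open bins and bands ($[lo, hi)$) make every nucleus fall in exactly
  one bin; ties at a threshold classify negative; renormalization is
  idempotent; degenerate profiles (no positive bin mean) raise errors
  rather than returning silent zeros.
* TIFF output is one 32-bit-float page per channel with intensities mapped
  to [0, 1] by a recorded scale and offset; channel names, pixel size and
  the intensity mapping live in a JSON sidecar, which round-trips images
  to within float32 precision.
* Every derived seed stays below 2³¹; all pipeline outputs are
  deterministic functions of (config, seed), and plots are pure views of
  the CSVs.
* Nuclei straddling the colony boundary are kept (distance filtering is
  left to the radial profile's maximum radius), and whether the original
  analysis excluded border-touching colonies is unknowable from the
  method description — they are rejected here with an explicit reason so
  the choice is auditable.

## Problem sizes in the validation suites

The test and acceptance suites size their simulations for a single CPU:
full-pixel validation (profile shape, fraction recovery, colony geometry)
runs on 500 µm colonies at 1 µm/px with 1500–1800 nuclei; the
200-replicate phenotype-separation study generates per-nucleus records
directly from the generator's measurement model (layout + activation +
intensity noise, reusing a pool of 12 layouts) rather than re-rendering
12 000 images whose segmentation accuracy is already established by the
pixel-level suites; and the 200-replicate neuruloid ordering study renders
at 4 µm/px, where area-fraction errors remain far below the effect sizes
being ordered. The family-wise error simulation (4 groups, n = 15, 2000
replicates) uses the analytic equivalence between "any adjusted p < α"
and "max |T| exceeds the α critical value", spot-checked in the tests.

# Known limitations

* Classical segmentation replaces trained pixel classifiers; colonies with
  strong intensity inhomogeneity or non-convex shapes would need the
  thresholding and boundary steps revisited.
* Only circular 500 µm micropatterns are supported; no angular profiling,
  no 3-D stacks (inputs are assumed max-projected), no vendor formats
  beyond TIFF.
* The Dunnett implementation assumes equal within-group variances (pooled
  SD); no mixed-effects layer across experimental batches is provided.
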