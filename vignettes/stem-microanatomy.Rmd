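---
title: "Stem microanatomy from cross-section CT: models and design choices"
author: "stemCT authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stem microanatomy from cross-section CT: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemCT)
```

## Scope

stemCT is a desk-scale reimplementation of a stem microanatomical phenomics
pipeline for maize basal internodes: cross-section CT-like images are
segmented into concentric zones and vascular bundles; 32 traits are computed
per section, including engineering-mechanics descriptors of the bundle
population; three-point-bending records are converted to bending moments;
multi-environment trait tables are analysed with a random-effects model for
variance components, heritability and BLUPs; and trait subsets are evaluated
as predictors of bending strength. Because the real image corpus is large and
externally archived, the package ships a synthetic-data module that generates
sections with exact ground truth, so every downstream stage is testable
without downloads. Everything is deterministic under explicit seeds.

## The synthetic section model

A section is an axis-aligned ellipse (semi-axes $a \ge b$) on a dark
background, with three concentric zones: a thin dense epidermis (EZ), a
bundle-rich periphery (PZ) and an inner zone (IZ) with fewer, larger bundles.
Default geometry mirrors the acquisition scale of stem micro-CT: 15 µm/px,
a 1250 × 1250 px frame, and semi-axes 8.8 × 7.8 mm (a third-internode-scale
section). Bundles are disks with lognormal radii (PZ median 140 µm, IZ median
260 µm, $\sigma_{\log} = 0.15$), placed by rejection sampling under three
constraints: centroid separation of at least `min_separation_um` (default
500 µm), a free surface gap of at least 150 µm between disks, and full
containment in the declared zone. Grey levels follow CT contrast polarity
(dense tissue bright): background 20, ground tissue 100, bundles 180,
epidermis 230, then Gaussian blur (σ = 1 px) and additive Gaussian noise
(σ = 6 grey levels). An inversion flag covers the opposite polarity.

Defaults were chosen once, at scale plausibility: published stem CT work
reports pixel size and zone nomenclature but no spatial statistics of the
bundle population, so counts (110 PZ + 50 IZ by default), radii and spacing
are realistic for a maize internode at this resolution rather than calibrated
to any measured section. The 500 µm separation sits comfortably below the
random-sequential-packing limit of the periphery band; the earlier candidate
default of 700 µm was at the jamming edge and made placement failures likely.

**Zone geometry.** Zones are *depth bands*: a pixel belongs to EZ if its
Euclidean distance to the section boundary is at most $t_{EZ}$ (default
0.24 mm), to PZ for depths in $(t_{EZ}, t_{EZ} + t_{PZ}]$ (default
$t_{PZ} = 2$ mm), else to IZ. The same definition — erosion of the stem mask,
i.e. thresholding its distance transform — is used by the segmenter, so
simulator truth and measurement share one geometry. For an ellipse the depth
band is bounded by inner parallel curves, not by concentric smaller ellipses;
the two differ by several pixels near the diagonals, enough to corrupt
per-zone bundle counts at the PZ/IZ boundary if mixed. Analytic zone areas
use the convex inner-offset formula $A(d) = A - P d + \pi d^2$, exact while
$d < b^2/a$ (true for the defaults).

## Segmentation

The published pipeline uses a learned semantic-segmentation stage whose
weights are not available; stemCT substitutes a classical detector with the
same interface, so a learned detector can be slotted in later:

1. **Stem**: global Otsu threshold, morphological closing, hole filling,
   largest connected component.
2. **Zones**: distance-transform bands as above.
3. **Candidates**: large-window median background correction (radius 45 px),
   Gaussian smoothing (σ = 2 px), adaptive threshold at
   median + 4 × MAD of the corrected in-stem intensities (with a 2-grey-level
   floor for the noise-free limit), and a watershed whose marker depth
   (h-maxima height) is 0.5 × MAD. Detection excludes a stem-boundary margin
   equal to $t_{EZ}$, since the epidermis is bundle-free by definition.
4. **Filtering**: each candidate is refined to its half-maximum support (the
   peak is the 95th percentile of the smoothed corrected intensity in the
   region; the cut is applied to the unsmoothed corrected image, whose
   sharper edge keeps the half-maximum contour on the true object radius —
   cutting on the smoothed image biases disk areas low by roughly
   $\sigma^2/r$ in radius). Acceptance requires area in [0.005, 1.5] mm²,
   solidity ≥ 0.70, eccentricity ≤ 0.97 and mean intensity at or above the
   in-stem median; rejected candidates are kept with their reasons.
5. **Zone assignment** is by the zone label at the bundle centroid; epidermis
   hits are reassigned to PZ and logged.

All constants are exposed in `seg_config()` and were fixed against
rendered-disk fixtures. On default synthetic sections the detector reaches
recall and precision of 1.0 and a matched-area R² above 0.999; this
certifies the geometry of the pipeline, not performance on real tissue,
where texture, ring artefacts and partial-volume effects are absent from the
simulator.

## The 32 traits

Canonical names and order are in `trait_names()`. Stem size and shape
(SZ\_\*) come from the stem mask: area by pixel count, perimeter from a
boundary contour subsampled every 5 points (suppressing pixel-staircase
bias), long/short axis from the mask's second-moment best-fit ellipse. Zone
areas are pixel counts of the depth bands; EZ/PZ thicknesses are means of the
stem distance transform along each band's inner boundary, and IZ thickness is
the inradius of IZ (its maximal distance-transform value). Bundle counts,
areas, densities (count per mm² of the carrying region) and area ratios are
per zone and whole-section.

The mechanical descriptors treat bundles as point masses $(A_i,
\mathbf{c}_i)$:

$$\mathrm{MOA} = \sum_i A_i y_i^2, \qquad \mathrm{PMOI} = \sum_i A_i r_i^2,$$

with $y_i$ the distance to the neutral axis and $r_i$ the distance to the
section centroid. PMOI decomposes exactly into the area moments about the
long and short principal axes (MOIAL + MOIAS, the perpendicular-axis
identity), which the test-suite asserts at 1e-9 relative on every computed
vector. `ave*` traits divide by the bundle count, consistent with the
`VB_Aave` naming. Units: mm, mm², mm⁻², mm⁴; computation is in µm internally
and converted once at assembly.

Two conventions were genuinely open and are configurable:

* **Neutral axis.** Whether MOA is taken about the loading axis, the image
  horizontal or a principal axis is not fixed by the trait inventory; the
  default is the image horizontal through the section centroid (a bending
  rig loads vertically in the image frame), which keeps MOA distinct from
  MOIAL. `axis_convention()` switches to either principal axis.
* **Per-bundle normalisation.** `ave*` traits divide by VB_N rather than by
  section area; with VB_N = 0 they are emitted as missing, never 0, to avoid
  biasing downstream regressions.

Sample-level aggregation over a slice stack is the per-trait median (robust
to occasional bad slices), with mean, SD and slice count reported.

## Bending moments

For a three-point bending test with support span $L$,
$\mathrm{BM} = F L / 4$: `compute_bmmax()` uses the global maximum load (no
failure-detection heuristics), `compute_bm10()` the load at 10 mm crosshead
displacement, linearly interpolated between the bracketing samples
(instrument exports are dense; higher-order fits add nothing). Spans are
accepted in cm or m and normalised; output is always N·m. The elastic
modulus is out of scope — testing machines report it directly.

## Variance components, heritability, BLUPs

Multi-environment tables follow
$$Y_{ikm} = \mu + g_i + \tau_k + (g\tau)_{ik} + \delta_{(k)m} +
\varepsilon_{ikm},$$
with line, environment, line-by-environment and replicate-within-environment
effects all random. `fit_variance_components()` fits this by REML via lme4
(bobyqa, tightened convergence), which enforces non-negative components by
parameterisation; `vc_moments()` provides the independent balanced-design
expected-mean-squares solution used as a cross-check — on balanced data the
two agree to better than 1e-4 relative. Broad-sense heritability on an
entry-mean basis is
$$H^2 = \frac{V_g}{V_g + V_{GL}/L + V_e/(LR)}.$$

Line values are genotype BLUPs (shrunken line-mean deviations) by default; a
BLUE mode refits with genotype fixed, because both conventions are common in
multi-environment trials and source descriptions are often ambiguous between
them. One numerical limitation is documented rather than patched: as
$V_e \to 0$ the REML parameterisation (random-effect variances profiled
against the residual) becomes degenerate below roughly $V_e \approx 10^{-5}$
on unit-scale data; the no-shrinkage limit is therefore verified through the
exact balanced-design identity $\mathrm{BLUP}_i = \kappa\,(\bar y_i - \bar
y)$ with $\kappa = V_g / (V_g + V_{GL}/L + V_e/(LR))$, not by fitting at
numerically zero residual variance.

## Predicting bending strength from traits

The protocol evaluates five named feature sets (all 32 traits; 5 stem; 21
vascular-bundle; 6 zone; the top-five key traits VB_A, PZ_VB_A, PZ_T, PZ_A,
MOA) under fivefold cross-validation with out-of-fold scoring only: RMSE,
pooled adjusted R² (Ezekiel form, $1-(1-R^2)(n-1)/(n-p-1)$) and the
out-of-fold Pearson correlation — the last because "prediction precision" is
reported ambiguously in the phenomics literature. The model registry holds
ridge (glmnet, fixed small penalty), ordinary least squares, a random forest
frozen at 100 trees of depth 10, an AdaBoost.R2 regressor over depth-4 CART
trees (implemented in-package; no boosting-regression package is a
dependency), epsilon-SVR with an RBF kernel, and a small weighted-decay
feed-forward network (5 hidden units, decay 0.1). The default model list is
the five classic families; the network is opt-in. Hyperparameters are frozen
rather than searched: at the benchmark's sample sizes a full grid search
adds variance without changing the ranking of feature sets.

Recursive feature elimination removes the lowest-importance feature under
the base estimator (ridge coefficient magnitude on standardized features by
default, random-forest permutation importance optionally) until k remain,
reporting the full elimination order and the cross-validated RMSE of each
intermediate subset. Fold assignment is drawn once from the protocol seed
(default 2021) and recorded in every report.

The planted-signal benchmark (`simulate_trait_benchmark()`) puts a linear
signal explaining 70% of target variance on the five key traits and pure
noise on the other 27, at n = 400. On it, RFE recovers the informative set in
at least 18 of 20 seeds, ridge on the informative set scores a pooled
adjusted R² within 0.05 of the planted 0.70, and a permuted-target null stays
at or below 0.05. The benchmark's traits are independent Gaussians; real
microanatomical traits are strongly correlated (areas, moments and zone
dimensions share factors), so RFE selections on real data identify
predictive *sets*, not uniquely important individual traits.

## Problem sizes and numerical choices

The test-suite works at two scales: a 420 px section (16 + 6 bundles) for
unit tests, and 20 full-scale sections (1250 px, 160 bundles) for the
end-to-end validation; the variance-component recovery uses 100 simulated
datasets of 200 lines × 2 environments × 3 replicates, and the prediction
benchmark 20 seeds at n = 400. Watershed label collisions resolve in
deterministic raster order; RFE importance ties drop the first (column-order)
feature; zone thickness uses the distance-transform convention above (an
area-over-perimeter alternative was rejected for non-circular sections).
Degenerate inputs error early with specific messages: empty curves, negative
loads, single-environment tables, missing zones, unplaceable bundle
requests.

## Known limitations

* The simulator has no ring artefacts, beam hardening, texture or
  partial-volume effects; passing its oracle bounds geometry errors only.
* Bundles are circular disks; real bundles are elliptical with a
  sclerenchyma sheath, so solidity/eccentricity filters are exercised only
  near their accept side.
* The zone model assumes fixed band depths; an adaptive PZ/IZ boundary
  (radial bundle-size profile) is a documented extension point, not a tested
  path.
* `vc_moments()` requires balance; unbalanced tables go through REML only.
* Three-dimensional structure (bundle tracking along the internode, volume
  moments) is out of scope.
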