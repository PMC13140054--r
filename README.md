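# stemCT

Microanatomical phenotyping of plant stem cross-sections from micro-CT
imagery, aimed at lodging-resistance research in maize. A stem's resistance
to bending is carried largely by its vascular bundles — dense strands that
appear as bright blobs in CT cross-sections — and by how they are arranged
across the section. stemCT turns cross-section images into a 32-trait
microanatomical profile, links it to measured bending mechanics, and
provides the quantitative-genetics and prediction layers used in
multi-environment phenomics studies.

The package covers five stages, each usable on its own:

1. **Synthetic data** (`section_spec()`, `simulate_cross_section()`,
   `simulate_phenotypes()`, `simulate_bending_curve()`,
   `simulate_trait_benchmark()`): CT-like sections with exact ground truth
   (bundle centroids, radii, zones), multi-environment phenotype tables from
   a random-effects model, and bending-curve fixtures. All deterministic
   under explicit seeds.
2. **Segmentation** (`segment_section()` and its parts): Otsu stem masking,
   distance-transform zone bands (epidermis EZ / periphery PZ / inner IZ),
   background-corrected adaptive thresholding plus marker-controlled
   watershed for bundle candidates, and geometric/morphological filtering
   with per-candidate rejection reasons.
3. **Traits** (`compute_section_traits()`, `truth_traits()`,
   `aggregate_slices()`): the 32 traits of `trait_names()` — stem size and
   shape, zone areas and thicknesses, bundle counts/areas/densities/ratios
   per zone, and the section-mechanics descriptors

   MOA = Σ Aᵢ·yᵢ² (moment of area about the neutral axis),
   PMOI = Σ Aᵢ·rᵢ² (polar moment of inertia about the section centroid),
   with its exact decomposition PMOI = MOIAL + MOIAS about the principal
   axes, all with bundles as point masses (area, centroid).
4. **Bending** (`compute_bmmax()`, `compute_bm10()`): three-point-bending
   moments BM = F·L/4 at peak load and at 10 mm displacement, with linear
   interpolation and cm/m span normalisation.
5. **Quantitative genetics and prediction** (`fit_variance_components()`,
   `heritability()`, `compute_blups()`, `rfe_rank()`, `evaluate_models()`,
   `compare_feature_sets()`): REML variance components of
   Y = μ + g + τ + gτ + δ + ε, broad-sense heritability
   H² = Vg/(Vg + V_GL/L + Ve/(LR)), genotype BLUPs/BLUEs, recursive feature
   elimination and five cross-validated regression families scored by RMSE
   and adjusted R².

See `vignettes/stem-microanatomy.Rmd` for the models, parameter defaults and
design decisions.

## Worked example

Simulate a full-scale section, segment it, and compare measured traits with
the analytic ground truth:

```r
library(stemCT)

sim <- simulate_cross_section(section_spec(seed = 7))
seg <- segment_section(sim$image, pixel_size_um = 15)

m <- match_to_truth(seg$bundles, sim$truth)
c(recall = m$recall, precision = m$precision,
  area_r2 = cor(m$matches$true_area_um2, m$matches$det_area_um2)^2)
#>    recall precision   area_r2
#> 1.0000000 1.0000000 0.9999072

tv <- compute_section_traits(seg$zones, seg$bundles, 15)
tt <- truth_traits(sim$truth, sim$spec)
round(rbind(measured = tv, truth = tt)[, c("SZ_A", "PZ_T", "VB_N", "VB_A", "MOA", "PMOI")], 3)
#>             SZ_A PZ_T VB_N   VB_A     MOA    PMOI
#> measured 216.284    2  160 18.137 234.501 532.912
#> truth    215.639    2  160 18.246 236.194 536.660
```

All 160 simulated bundles are recovered with no false positives; areas,
zone geometry and the mm⁴-scale moments agree with the analytic oracle to a
few percent. Downstream, a phenotype table and bending record:

```r
tab <- simulate_phenotypes(200, n_envs = 2, n_reps = 3, mu = 10,
                           Vg = 2, V_env = 1, V_GL = 0.5, V_rep = 0.2,
                           Ve = 1, seed = 5)
fit_variance_components(tab)
#> Variance components (REML):
#>       Vg    V_env     V_GL    V_rep       Ve
#> 1.857925 0.055428 0.519775 0.370651 1.004849
#> L = 2 environments, R = 3 replicates; H2 = 0.8130

curve <- simulate_bending_curve(f_max = 120, d_peak = 15, seed = 1)
compute_bmmax(curve, span = 45, span_unit = "cm")   # 120 N x 0.45 m / 4
#> [1] 13.5
```

A command-line interface wrapping these functions is installed at
`system.file("cli", "stemct.R", package = "stemCT")` with subcommands
`simulate`, `segment`, `traits`, `bending`, `blup` and `predict`; every
invocation is byte-reproducible under a fixed seed.

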