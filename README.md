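# endograd

Quantifying protein distribution gradients in the wheat grain endosperm
from stained light-microscopy sections.

## The problem

The starchy endosperm of the wheat grain — the tissue milled into white
flour — is not homogeneous: storage (gluten) protein is concentrated in
the outer endosperm, next to the aleurone layer, and declines towards the
centre of the grain's two lobes. The steepness of this gradient matters
for milling, because protein-rich outer endosperm adheres to the bran and
is lost from white flour. `endograd` implements an image-analysis
pipeline that turns a stained grain cross-section into quantitative
gradient estimates, for plant scientists studying how growth conditions
(post-anthesis temperature, nitrogen supply) reshape protein deposition.

Input is an RGB micrograph of a 1-µm section stained with Naphthol Blue
Black (protein stains dark blue-black), a manually drawn endosperm
outline, labelled training regions, and a grain nitrogen measurement.
The pipeline is:

1. **Classification** — supervised maximum-likelihood (Gaussian)
   classification assigns each pixel inside the outline to protein or
   background. Each class *c* is a multivariate normal over RGB; a pixel
   *x* goes to the class maximising

   ln π<sub>c</sub> − ½ ln |Σ<sub>c</sub>| − ½ (x − µ<sub>c</sub>)ᵀ Σ<sub>c</sub>⁻¹ (x − µ<sub>c</sub>),

   with equal priors, class means and covariances estimated from training
   regions, and covariance regularised as Σ + εI. Each image is analysed
   several times with independent training sets (three by default) to
   expose training-sample variation.
2. **Zonation** — K concentric equal-width zones (default K = 5) are
   rendered inward from the outline using the Euclidean distance
   transform, with band width d<sub>max</sub>/K, so zones span the full
   outer-to-inner range whatever the grain size. Per-zone protein
   concentration is the by-area fraction: protein area / zone area.
3. **Body metrics** — individual protein bodies are 8-connected
   components of the classified mask; each body's area (µm²) and the
   shortest Euclidean distance from its centroid to the outline are
   measured, and per-zone size histograms built.
4. **Calibration** — a conversion factor
   *cf* = (N% × 5.7 / 100) / (total protein area / total grain area)
   links image fractions to chemically measured grain protein so that the
   area-weighted mean calibrated concentration equals the measured
   protein percentage exactly.
5. **Gradient statistics** — per-group ordinary-least-squares trends of
   calibrated concentration (and of log body area) against distance from
   the aleurone layer, in units per µm, with a distance-squared
   lack-of-fit F-test and descriptive slope comparisons between groups.

A synthetic section generator (`generate_section()`) produces two-lobed
endosperm images with programmed gradients and exact ground truth, so
every stage is testable without real micrographs. Small utilities compute
thermal-time-equivalent sampling days between temperature regimes and
nutrient-solution nitrogen supply.

## Worked example

Generate a synthetic section, classify with three replicated training
sets, measure zones, calibrate against a 2.0 % grain nitrogen
measurement, and fit the gradient:

```r
library(endograd)

cfg <- synth_config(canvas = c(400L, 600L), seed = 1)
gen <- generate_section(cfg)
trainings <- lapply(1:3, function(i)
  generate_training_rois(gen, seed = i, replicate_id = i))
masks <- classify_replicates(gen$image, gen$mask, trainings)

part <- make_zones(gen$mask, 5)
zm   <- measure_zones(part, masks[[1]], scale = 1)
zm
#>   zone mid_distance_um zone_area_um2 protein_area_um2 raw_fraction replicate_id
#> 1    1           13.34         34408             6792       0.1974            1
#> 2    2           40.02         30330             5860       0.1932            1
#> 3    3           66.71         25734             4819       0.1873            1
#> 4    4           93.39         21264             3883       0.1826            1
#> 5    5          120.07         13830             2439       0.1764            1

rec <- compute_conversion_factor(2.0, zm)
rec
#> calibration_record: N 2.000%, protein 11.40%, image fraction 0.1895, factor 0.6016

cal <- apply_calibration(rec, zm)
fit <- quadratic_check(fit_gradient(
  data.frame(distance_um = cal$mid_distance_um,
             response = cal$calibrated_concentration),
  response = "concentration"))
fit
#> gradient_fit: concentration ~ distance
#>   slope       -0.0118776  (se 0.0004283) per um
#>   intercept      12.0648  (se 0.03283)
#>   n = 5, R^2 = 0.9961, lack-of-fit (distance^2) p = 0.2711
```

Reading the output: the outermost zone's centre sits 13.3 µm inside the
outline and carries a raw by-area protein fraction of 0.197, falling to
0.176 in the innermost zone. The conversion factor 0.6016 rescales image
fractions so that their area-weighted mean equals the chemically measured
11.4 % protein. The fitted gradient is −0.0119 concentration points per
µm (negative: more protein near the aleurone layer), and the
distance-squared check finds no evidence of non-linearity (p = 0.27).

Protein bodies from the same section:

```r
bodies <- body_distances(extract_bodies(masks[[1]], 1), gen$mask, 1, part)
nrow(bodies)
#> [1] 838
fit_gradient(log_transform_areas(bodies), response = "log_body_area")
#> gradient_fit: log_body_area ~ distance
#>   slope      -0.00128674  (se 0.0004749) per um
#>   intercept      3.29222  (se 0.03179)
#>   n = 838, R^2 = 0.0087
```

Mean log body area declines by 0.0013 per µm of inward distance: bodies
are larger near the aleurone layer. Batches of real sections are driven
by a CSV manifest through `run_batch()`; a thin command-line front end
lives at `inst/cli/endograd.R` (subcommands `simulate`, `run`,
`thermal-time`, `nitrogen-mass`).

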