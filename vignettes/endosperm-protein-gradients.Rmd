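---
title: "Measuring protein distribution gradients in grain endosperm sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring protein distribution gradients in grain endosperm sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endograd)
```

`endograd` estimates how storage protein is distributed across the wheat
grain endosperm from light-microscopy sections stained with Naphthol
Blue Black. This vignette is the package's account of the method: the
models at each stage, their assumptions, the tunable parameters and why
their defaults are what they are, what the synthetic validation does and
does not demonstrate, and the numerical conventions adopted where the
procedure left genuine choices open.

## The measurement model

A section enters the pipeline as an RGB raster with a physical scale in
µm/pixel (always user-supplied — magnification alone does not determine
the scale, so it is never guessed from metadata) together with a manually
drawn endosperm outline placed just inside the aleurone layer. Everything
downstream uses one coordinate convention: (row, col) with the centre of
matrix element (i, j) at coordinate (i, j), and polygons rasterised by
the pixel-centre-inside rule, boundary inclusive — a deterministic tie
rule, so masks are reproducible to the pixel.

### Pixel classification

Stained protein is detected by supervised maximum-likelihood
classification. Each class — protein, plus one or more background
subclasses covering the tones of unstained tissue — is a multivariate
Gaussian over (R, G, B). A pixel $x$ inside the outline is assigned to
the class maximising

$$\ln \pi_c - \tfrac12 \ln \lvert\Sigma_c\rvert
  - \tfrac12 (x - \mu_c)^\top \Sigma_c^{-1} (x - \mu_c),$$

with ties broken toward the lowest class index (determinism again). The
modelling assumptions are that class colours are roughly Gaussian with
possibly correlated channels — hence full covariances, not diagonal —
and that no spatial information is needed: classification is strictly
per-pixel, with no smoothing or morphological clean-up afterwards.
Priors are equal across classes because training regions carry no
information about class abundance. Two parameters matter:

* `regularisation` (default `1e-3` on the 0–255 intensity scale) is a
  ridge added to each class covariance. Training regions drawn inside a
  uniformly stained body can be nearly single-coloured; the ridge keeps
  the covariance invertible without visibly moving decision boundaries.
* the training protocol itself: around ten protein regions spread across
  the grain plus enough background regions, repeated (three replicates
  by default) with different regions each time. The replicate masks are
  carried through the whole pipeline; `replicate_agreement()` reports
  pairwise agreement as a quality-control statistic, but no pass/fail
  threshold is imposed — judging classification adequacy remains with
  the analyst.

### Zonation

Concentric zones are defined on the Euclidean distance transform of the
mask: each in-mask pixel's distance to the nearest outside pixel centre,
with the canvas border counted as outside (a robustness rule; real
outlines sit well inside the frame). With $d_{\max}$ the deepest in-mask
distance and $K$ zones, band width is $d_{\max}/K$ and a pixel at depth
$d$ falls in zone $\min(K, \lfloor d / (d_{\max}/K)\rfloor + 1)$ —
half-open bands, the single deepest pixel folded into zone $K$. Defining
bands on the distance transform (rather than by geometric buffering of
the outline polygon) was an open choice; the two differ by sub-pixel
amounts on concave outlines, and the distance-transform definition is
exact, fast, and shares its machinery with the body distances.

Because $d_{\max}$ is computed per image, zones adapt to grain size.
That is why the modelling variable is not the zone index but the
physical mid-band distance $(k - \tfrac12) \cdot d_{\max}/K \cdot
\text{scale}$ in µm: distances are comparable across grains of different
sizes, zone indices are not. $K = 5$ is the default; `choose_zone_count()`
re-fits the fraction-versus-distance regression for candidate $K$ (3–7
by default) and picks the best coefficient of determination, preferring
5 on ties within $10^{-6}$.

Per-zone protein concentration is by-area: protein pixels over zone
pixels, dimensionless, converted to µm² through scale². Zone areas sum
exactly to the mask area and protein areas to the total protein area —
these conservation identities hold at pixel-count level and are asserted
in the tests.

### Protein bodies

Bodies are 8-connected components of the classified mask: at 1-µm
section thickness diagonally touching stained pixels are continuous
deposits. The midpoint is the pixel centroid (robust for irregular
shapes; a bounding-box centre is not), and the body's distance is the
shortest Euclidean distance from that centroid to the outline polygon,
computed as a minimum over point-to-segment distances. `min_area_px`
(default 4, 1 disables) drops components smaller than four pixels as
classification noise; the default is deliberately permissive because
small bodies genuinely dominate stained sections, and whether the
original analysis counted single-pixel objects is unknown. Size
histograms use 12 log-spaced bins by default, matching the strongly
right-skewed size distribution.

### Calibration

By-area fractions confound protein amount with staining and detection
efficiency, grain water content, and protein packing density. The
calibration anchors them to a chemical measurement: with grain nitrogen
$N\%$ and a nitrogen-to-protein multiplier $m$ (default 5.7, the
standard wheat factor; set $m = 1$ to supply protein % directly),

$$\text{cf} = \frac{N\% \cdot m / 100}
  {\text{total protein area} / \text{total grain area}},
\qquad
\text{calibrated}_k = \text{raw}_k \cdot \text{cf} \cdot 100 .$$

The printed source of this equation is typographically ambiguous; this
orientation is adopted because it is the only one under which applying
the factor achieves the stated purpose — the area-weighted mean of the
calibrated zone concentrations equals the measured protein percentage
*exactly* (an algebraic identity, asserted to $10^{-10}$), so
between-treatment differences in detection efficiency cancel. Because
the factor is a positive scalar per grouping, zone ordering and gradient
sign are invariant under calibration. One factor is computed per
treatment × experimental replicate by default (pooling that grouping's
sections), per section optionally.

### Gradient statistics

`fit_gradient()` fits ordinary least squares of a response on distance
in µm: calibrated concentration (per-zone values averaged over
classification replicates) or natural-log body area (pooled across
replicates with ids retained; natural rather than base-10 log is an
arbitrary convention fixed once — either stabilises the skewed size
variance). A negative slope means more protein, or larger bodies, near
the aleurone layer. `quadratic_check()` adds a distance-squared term and
reports the nested-model F-test p-value; the linear model is never
replaced automatically, and exactly linear data are reported as $F = 0$,
$p = 1$ rather than a 0/0. `compare_groups()` gives pairwise slope
differences with Welch-type z statistics.

These are deliberately *fixed-effects* summaries. The full experimental
design is nested — rooms × blocks, pots, section replicates, zones,
analysis replicates — and belongs in a REML linear mixed model, which is
standard software and out of scope here; the package's contribution is
the measurement pipeline, so it exports tidy per-zone and per-body
tables for exactly that external analysis, and flags its own group
comparisons as descriptive.

## The synthetic validation

No micrographs ship with the package; instead `generate_section()`
produces sections with exact ground truth. The generator emulates the
features the pipeline is sensitive to:

* a two-lobed outline with a crease indentation — concave, like a wheat
  cross-section, so the concave-polygon distance code is exercised. The
  crease is carved into the outline (whether a real manual outline would
  include or exclude the crease lumen is unrecorded; the mask format
  permits either, and the fixtures deliberately include the
  indentation);
* a programmed by-area protein fraction falling linearly with inward
  distance (default 0.20 at the outline, slope −2 × 10⁻⁴ per µm —
  realistic 12–20 % protein fractions);
* body areas drawn log-normally with mean log area falling linearly
  with distance (default log 30 µm² at the outline, −1.5 × 10⁻³ per µm,
  log-sd 0.5): abundant small bodies, few large ones, larger near the
  outline;
* stain colours: protein RGB (45, 45, 90), background (205, 195, 185),
  per-channel sd 12 — plausible dark blue-black on pale counterstain,
  purely cosmetic and configurable.

Bodies are placed as discrete ellipses with hard pixel membership (no
anti-aliasing, so truth areas are exact pixel counts) and a one-pixel
clearance from already-placed protein, sequentially and deficit-driven
across zones until each zone reaches its programmed coverage. The
generator is parameterised by the area-fraction gradient directly,
rather than by a body-count intensity, because the quantities the
pipeline must recover — per-zone fractions and the concentration slope —
are then controlled exactly rather than indirectly through the random
size marks; the implied count density is fraction over mean body area.
All randomness flows from one integer seed; identical configurations are
byte-identical.

`synth_treatment_config()` provides two presets mirroring the direction
(not the magnitude) of the temperature effect on endosperm protein:
"control" (fraction 0.18 at the outline, slope −2 × 10⁻⁴ per µm, size
slope −1.2 × 10⁻³) and "high_temperature" (0.24, −3.5 × 10⁻⁴,
−2.0 × 10⁻³) — higher overall concentration and steeper negative
gradients under heat.

What passing the synthetic suite shows: the geometry, accounting and
estimation are correct — fractions, areas and distances are conserved
and recovered, and programmed gradients are re-estimated within stated
tolerances through the *entire* pipeline including classification. What
it does not show: performance on real histology. Real sections have
stain-intensity drift across the grain, cell walls and subcellular
texture, fused protein masses in mature grain, section artefacts, and
hand-drawn outlines of varying tightness; none of these are simulated,
which is precisely why the replicated-training protocol and the
agreement diagnostics exist.

### Validation problem sizes

The recovery study runs the full pipeline on a 1000 × 1500 px section at
1 µm/px with three training replicates (seed-fixed) and checks: maximum
per-zone fraction error below 0.02; body recall and precision at least
0.95 under centroid matching within 2 px (against truth bodies at the
same minimum-size filter); concentration slope within 15 % and log-size
slope within 20 % of programmed values. Sign recovery of both negative
gradients is checked over 20 seeded runs at 800 × 1200 px with a single
training replicate, and the control versus high-temperature contrast
over four seeded pairs at 400 × 600 px — sizes chosen so each property
holds with a comfortable signal-to-noise margin while the whole study
stays desk-scale.

### Known limitations

* **Size-gradient attenuation.** Non-overlapping placement rejects a
  candidate body that touches existing protein, and large bodies collide
  more often, especially in dense outer zones. The accepted size
  distribution is therefore tilted slightly small where coverage is
  high, attenuating the realised size gradient relative to the
  programmed law by an approximately constant offset. The relative bias
  consequently grows as the inward distance range shrinks: about 12 % at
  the full validation size, but large enough on very small canvases to
  flip the fitted sign in a noticeable fraction of runs. This is a
  property of the generator's placement model, not of the measurement
  pipeline, and is the reason sign-recovery is validated at 800 × 1200
  px rather than on miniature fixtures.
* **Merged deposits.** In real mature grain, protein bodies fuse; a
  per-pixel classifier followed by connected components measures the
  fused mass, not the biological bodies. The generator's discrete-body
  model does not probe this regime (truth is still defined as connected
  components of the rendered raster, so any touching deposits are
  honestly merged).
* **Label-image outlines.** When a mask arrives as a 0/255 label image
  rather than a polygon, the outline is reconstructed as the 0.5-level
  marching-squares contour, which runs half a pixel outside the
  foreground centres; body distances measured against it differ from the
  polygon-input case by sub-pixel amounts.
* **Inference.** Slope standard errors treat observations as
  independent, ignoring the nested design; use the exported tables in a
  mixed-model framework for publication-grade inference.

## Experiment-design utilities

Two small calculators round out the package. `daily_thermal_time()`
uses a square-wave day/night profile — photoperiod-weighted mean
temperature minus a base of 4.1 °C (the standard wheat base); symmetric
day/night transition ramps leave the daily mean unchanged and are
ignored. `equivalent_day()` converts sampling days between temperature
regimes by equating accumulated thermal time, rounding to the nearest
day, halves away from zero:

```{r}
ctrl <- thermal_regime(20, 15, day_hours = 16, base_temp = 4.1)
hot  <- thermal_regime(28, 15, day_hours = 16, base_temp = 4.1)
c(daily_thermal_time(ctrl), daily_thermal_time(hot))
c(equivalent_day(ctrl, 14, hot), equivalent_day(ctrl, 21, hot))
```

`nitrogen_mass()` totals the nitrogen supplied by a nutrient recipe
(molarity × N atoms × 14.0067 mg/mmol × volume × applications).
Chelator-bound nitrogen (FeNaEDTA) is excluded by default — it is not a
plant nitrogen source in the usual accounting — and can be included with
a flag:

```{r}
c(high = nitrogen_mass(trial_nutrient_recipe("high")),
  low  = nitrogen_mass(trial_nutrient_recipe("low")))
```

## Degenerate inputs and error behaviour

Deliberate hard errors rather than silent recovery: non-RGB images;
non-positive scale; empty or disconnected mask regions; a training class
with fewer than four pixels (covariance not estimable) or zero variance
with zero regularisation; singular covariance at classification time;
$K < 2$ or a mask with no interior depth; a zone of zero area; zero
protein area at calibration (the factor is undefined); body midpoints
outside the mask (flagging upstream inconsistency — sub-pixel
excursions of boundary-body centroids past a traced outline are
tolerated); gradient fits with fewer than three observations or constant
distance; and a manifest grouping with no nitrogen entry, reported by
grouping key.
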