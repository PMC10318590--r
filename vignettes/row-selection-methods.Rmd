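---
title: "Row selection and plot trimming in plot-level remote sensing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Row selection and plot trimming: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question

Breeding trials of maize and sorghum are commonly planted as four-row plots.
When traits are extracted from UAV imagery and LiDAR on a row-segment basis,
the analyst must decide which rows to pool — all four (RS1234), the inner
pair (RS23), the outer pair (RS14), or a single row (RS1–RS4) — and whether
to trim a fixed length (here 40 cm) off both row ends to avoid alley
effects. Outer rows border neighboring genotypes and alleys, so they grow
under different competition; this *border effect* both inflates their means
and adds noise. `rowseg` implements the full evaluation loop: simulate a
trial with a known border effect, extract traits per row-segment selection,
score each scheme by entry-mean repeatability and by cross-validated yield
prediction accuracy, and compare schemes with factorial ANOVA and LSD letter
groupings.

# The synthetic trial generator

Everything downstream is exercised against a generator with known ground
truth (`trial_config()`, `simulate_trial()`). The latent "vigor" of row
$r$ of the plot carrying hybrid $i$ in replicate block $j$ is

$$ v_{ir} = \mu + G_i + R_j + b\,\mathbf{1}[r \in \{1,4\}] + e_{ir}, \qquad
   G_i \sim N(0, \sigma^2_G),\;
   e_{ir} \sim N(0, \sigma^2_e + s_b^2 \mathbf{1}[r \in \{1,4\}]). $$

Geometry defaults reproduce the standard trial layout: 3.05 m rows, 76 cm
row spacing, 76 cm alleys, a randomized complete block design with each
genotype once per block. The remaining defaults were fixed once, on the
reasoning below, and define the study conditions for every test:

| parameter | default | reasoning |
|---|---|---|
| `trait_mean` ($\mu$) | 1 | vigor is a unitless multiplier on trait scales |
| `genetic_variance` ($\sigma^2_G$) | 0.04 | 20% genetic CV, typical of diverse hybrid panels |
| `residual_variance` ($\sigma^2_e$) | 0.01 | plot-to-plot error half the genetic sd |
| `border_effect_mean_shift` ($b$) | +0.15 | border rows visibly larger (extra light), ~15% |
| `border_extra_sd` ($s_b$) | 0.10 | border competition roughly doubles row noise |
| `alley_end_shift` | +0.10 in a 0.40 m end zone | alley plants get the same kind of advantage |
| `plant_sd` | 0.05 | within-row plant-to-plant variation |
| `meas_sd` | 0.05 | per-plant, per-flight measurement error |
| `row_meas_sd` | 0.05 | per-row, per-overpass scene-level error |
| yield | $500 + 1200 \cdot \bar v_{\text{inner}} + N(0, 150^2)$ g m$^{-2}$ | ~1700 g m$^{-2}$ biomass with a realistic signal:noise |

No quantitative magnitude for the border effect on remote-sensing traits is
established in the literature, so the generator exposes it as a parameter
rather than hard-coding a value; the defaults above make the effect clearly
present but not caricatured.

Two design points deserve emphasis.

**Yield comes from the inner rows.** Trials of this type harvest rows two
and three, so simulated yield is a function of the inner-row latent means
only. This deliberately reproduces the favorable bias that inner-row
features enjoy in prediction — the comparison the analysis is about.

**Measurement error has a scene-level component.** Per-flight error is
split into a per-plant part (`meas_sd`) and a per-row, per-overpass part
(`row_meas_sd`) shared by every plant of a row in one flight — sensor
calibration, illumination and georeferencing act on the scene, not
independently per plant. The shared component is what makes end trimming
behave as observed in real trials: the trimmed and untrimmed views of a row
share the same overpass and the same plants except in the 40 cm end zones,
so trimming changes no systematic variance component and its ANOVA test
rejects at the nominal rate. With purely per-plant error, trimming would
carry a small artificial precision penalty (fewer plants averaged) that a
flight-replicated ANOVA eventually detects.

The renderers (`render_point_cloud()`, `render_rasters()`) turn the latent
trial into sensor products: ground returns plus canopy returns whose height
and density grow with thermal time and vigor; a ~1 cm RGB orthophoto with
green canopy disks against brown soil; and a ~4 cm, 15-band reflectance
raster mixing fixed soil and vegetation endmember spectra, with the NIR
plateau (bands ≥ 740 nm) scaled by local vigor. Scaling only the plateau
matters: scaling every band above 700 nm would cancel out of
normalized-difference indices built on the 750/705 nm pair. What the
renderers do *not* emulate: occlusion, multiple returns, radiative
transfer, orthorectification artifacts, sensor-specific noise, lodging,
weeds. Tests passing on this generator therefore show that the *analysis*
recovers known structure, not that any given field dataset satisfies the
model.

# Row-segment geometry

`build_grid()` forms one axis-aligned box per (plot, row): laterally the
full 76 cm row spacing centered on the row line; longitudinally from the
proximal-most to the terminal-most plant, so box lengths vary with
emergence. Boxes are half-open `[min, max)` so adjacent boxes never
double-count a point or pixel; millimeter overlaps from lateral plant
jitter are clipped to the shared midpoint. The grid is built once from an
early-season snapshot and reused for all flights; canopy material that
grows outside it later in the season is simply excluded — the mechanism
that explains why end trimming changes little. Trimming (`trim_box()`)
removes 0.40 m per end from the plant-derived box (not the nominal 3.05 m
plot), errors below a 0.5 m minimum length, and commutes with row
selection. A row segment with fewer than two emerged plants cannot define a
box and is flagged missing rather than raising an error.

# Traits

All traits pool points/pixels across the selected boxes rather than
averaging per-row values — the two differ only when rows differ in point
counts, and pooling is the direct generalization of a per-segment ratio
statistic.

* **CC** — vegetation fraction of RGB pixels, classified by HSV thresholds
  (defaults: hue strictly inside 60–180°, saturation > 0.15, value > 0.10;
  ties count as soil). Thresholds are configurable; published workflows cite
  HSV thresholding without universal values.
* **CC10** — fraction of all returns strictly above the 10th percentile of
  the *nonground* return heights. Taken literally over a single population
  the statistic is 90% by definition, so the nonground/all split is the
  operative reading; the alternative (percentile over all returns) remains
  selectable via `percentile_population = "all"`.
* **Height95** — 95th percentile of nonground heights.
* **PlotVolume** — 8 cm × 8 cm cells per box; each cell with a nonground
  return contributes its clipped area times
  $(p_{95}(z) + \min z)/2$.
* **Vegetation indices** — ten red-edge/NIR formulas (NDVI, GNDVI, mRENDVI,
  OSAVI, PRI, PSRI, SR800680, SR700670, VOG1, Carte1) averaged over
  vegetation pixels after an NDVI > 0.5 ground mask; bands are located by
  nearest-wavelength lookup within ±3 nm; pixels with undefined values
  (zero denominators) are excluded with a message. The OSAVI constant sits
  in the denominator, $1.16\,(R_{800}-R_{670})/(R_{800}+R_{670}+0.16)$, the
  standard form.

Percentiles everywhere use linear interpolation between order statistics
(type 7); no percentile convention is universal in the field, and the choice
is made explicit so oracle tests can reproduce it. Ground classification
defaults to a minimum-z-per-cell rule (0.5 m cells, 0.10 m threshold), but
synthetic truth labels can be passed through, so extraction can be tested
with and without classification error.

# Repeatability

Per (trait, flight, year, selection, trim) cell the two-variance-component
model $y_{ij} = \mu + H_i + R_j + \varepsilon_{ij}$ (hybrid random,
replicate fixed) is fit by REML, and entry-mean repeatability is

$$ H^2 = \frac{\sigma^2_H}{\sigma^2_H + \sigma^2_\varepsilon / \mathrm{rep}}. $$

The REML fit profiles the criterion down to the single variance ratio
$\lambda = \sigma^2_H/\sigma^2_\varepsilon$: the grouped covariance
structure gives a closed-form restricted likelihood per $\lambda$ in
$O(n)$, maximized by a deterministic Brent search on $\log(1+\lambda)$ over
$[0, e^{25}]$ with tolerance ~1e-12, which includes the $\lambda = 0$
boundary (negative genetic variance truncates to zero, so $H^2 = 0$ rather
than negative). On balanced complete data the estimates coincide with the
closed-form ANOVA estimators $\hat\sigma^2_H = \max(0, (MS_H - MS_E)/r)$,
$\hat\sigma^2_\varepsilon = MS_E$ (available as
`method = "anova_closed_form"`), and the tests additionally verify
agreement with an independent mixed-model implementation (lme4) on balanced
and unbalanced designs. Each flight date yields its own $H^2$; flights
within a thermal-time window then act as replicates in the factor analysis,
matching how window-level repeatability summaries average over flights.

# Phenology

Daily growing degree days are $[(T_{max}+T_{min})/2] - 10$ °C·day with both
temperatures clamped into [10, 30] °C before averaging, accumulated
inclusively from planting. Growth-stage windows are half-open —
vegetative [0, 650), flowering [650, 900), grain filling [900, ∞) — with a
boundary value assigned to the later stage. (Some summaries print the
flowering window with a 0 lower bound; the disjoint windows are used, the
overlap being read as typographical.)

# Yield prediction

Features are trait × flight values per plot entry (replicates of a genotype
are distinct entries). Prediction uses ε-SVR with the Gaussian kernel
$k(u, v) = \exp(-\sigma \lVert u - v\rVert^2)$ (kernlab backend, ε = 0.1)
under repeated k-fold cross-validation; when subpopulation labels are given
(temperate/tropical style), folds are dealt round-robin within each group,
so every fold's composition differs by at most one entry per group.
Standardization (center/scale) is computed on the training portion of each
fold only and applied to the test fold — a canary test verifies a wild
outlier placed in a test fold cannot move training-side predictions.

Hyperparameters are grid-searched: sigma over {1e-4, 1e-3, 1e-2, 0.1} (a
published version of this grid repeats "0.001"; the duplicated point is
read as a typo for 1e-4 and the grid is fully configurable) and cost over
{10, 50, 100, 150, 200, n}, where the token `"n"` resolves to the number of
features at run time. The selection granularity is one search per outer
repeat: the first fold's training portion is split into `inner_k = 5` inner
folds, the pair maximizing mean inner-fold correlation wins, and all k
outer folds of that repeat use it. Per-fold selection would be stricter but
k-times costlier; per-repeat matches the reference workflow's economy and is
recorded in the run metadata. Accuracy is the correlation of predicted and
observed yield per held-out fold; a run reports all fold correlations, their
mean and sd.

# Factor analysis

Repeatability (or repeat-level accuracy) observations are compared with a
fixed-effects linear model using type-I sums of squares in the order
`trim + year + selection + selection:year`. The generator produces balanced
data, so the order is immaterial; trim × anything interactions are not
modeled (trimming shows no interactions to exploit). Factors with a single
level (e.g. one simulated year) are dropped from the model rather than
erroring. A constant response is reported as F = 0, p = 1 for all terms.
Significance letters come from an unadjusted LSD at α = 0.05:
$LSD = t_{1-\alpha/2, df_e}\sqrt{2\,MSE/n}$ with the ANOVA error mean
square, harmonic-mean n under imbalance; letters are assigned to the means
in descending order as maximal runs whose extremes differ by at most the
LSD, which makes "share a letter" exactly equivalent to "within the LSD" —
a property the tests check against all-pairs t-tests.

# Problem sizes and determinism

Simulations are sized so the whole suite runs in minutes on one CPU: REML
calibration uses 200 simulated trials of 200 genotypes × 2 replicates
(true $H^2 = 0.8$); the border-effect study uses 50 trials of the default
100-genotype design with three flowering-window flights; the prediction
contrast uses 20 trials of a 20-genotype × 3-replicate design with
5-fold × 10-repeat cross-validation and the cost grid thinned to
{10, 100, n}. The direction of every contrast is structural, not
grid-dependent. All randomness fans out from one master seed through
stage-labeled substreams (`derive_seed()`), so adding a stage never
perturbs another stage's stream and rerunning a configuration reproduces
every numeric output exactly.

The pipeline's default trait path (`mode = "direct"`) generates trait
observations from the latent truth with the same error anatomy the
renderers produce; the sensor path (`mode = "render"`) renders clouds and
rasters range by range and extracts traits from them. The two agree to
r ≥ 0.97 per trait on rendered checks and the sensor path is exercised by
the unit tests; the direct path is the default because it runs in seconds
at trial scale.

# Known limitations

* The generator's border effect is additive and time-stationary; real
  border effects can grow with canopy closure.
* Rendered sensor products are geometric caricatures (no occlusion or
  radiometric effects), so absolute trait values are not comparable to any
  particular sensor — only the recovery of *relative* structure is tested.
* Repeatability treats replicate as fixed and ignores spatial trend; no
  spatial correction or BLUP extraction is provided.
* LSD is intentionally unadjusted for multiplicity, mirroring standard
  practice in this literature; with many levels its pairwise error rate is
  liberal.
* Multi-year data are simulated as independent trials with a year shift;
  genotype-by-year correlation structure is not modeled.
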