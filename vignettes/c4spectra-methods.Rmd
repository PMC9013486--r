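---
title: "Estimating C4 photosynthetic capacity from gas exchange and canopy spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating C4 photosynthetic capacity from gas exchange and canopy spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`c4spectra` implements a complete desk-scale pipeline for screening C4
germplasm for photosynthetic capacity: inversion of a C4 biochemical model
from gas-exchange response curves, prediction of the resulting traits
(and of specific leaf nitrogen SLN and leaf mass per area LMA) from
NDVI-masked canopy hyperspectral reflectance, and genotype-level
heritability of the predictions from row-column field trials. This
vignette explains the models, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## 1. The C4 photosynthesis model

Net CO2 assimilation `A` is the minimum of an enzyme-limited rate `Ac` and
an electron-transport-limited rate `Aj`, both functions of the
bundle-sheath CO2 partial pressure `Cs`:

* `Ac = (Cs - γ*Os) Vcmax / (Cs + Kc (1 + Os/Ko)) - Rd`
* `Aj = [(1 - x) Jt / 3] (1 - γ*Os/Cs) / (1 + 7 γ*Os / (3 Cs)) - Rd`

with whole-chain electron transport `Jt` the smaller root of the
non-rectangular hyperbola `θ Jt² - (I₂ + Jmax) Jt + I₂ Jmax = 0`,
`I₂ = PSabs × I_inc`. The supply side couples the mesophyll and bundle
sheath: `Cm = Ci - A/gm`, and
`Cs = Cm + (pump - A - Rm)/gbs` where the pump is PEP carboxylation
`Vp = Cm Vpmax/(Cm + Kp)` in the enzyme regime or the C4-cycle share of
electron transport `x Jt/φ` in the light regime, and `Rm = rm_ratio × Rd`.

Two presentation details deserve flagging:

* **The `Aj` form.** The electron-transport-limited expression is used in
  its standard C4 form shown above — the published rendering of this
  equation is typographically ambiguous, and the standard form is the one
  consistent with the surrounding supply equations.
* **Kinetic constants.** The defaults (`Kc` 1210 μbar, `Ko` 292 mbar,
  `Kp` 82 μbar, `γ*` 1.93e-4, `Os` 210 mbar, `gbs` 0.003 mol m⁻² s⁻¹
  bar⁻¹, `x` 0.4, `φ` 2, `Rm = 0.5 Rd`) are a documented set from the
  standard C4 modelling literature, fully overridable via
  `c4_constants()`. Fitted magnitudes (notably `Vpmax`) depend on the
  constant set used, so analyses should report it. CO2 mole fractions
  (ppm) are treated as numerically equal to partial pressures in μbar
  (1 bar total pressure). No temperature scaling is applied: all
  parameters are at-measurement values.

### Numerical solution

For given parameters the model is a one-dimensional fixed point in `A`:
`f(A) = A - demand(supply(A))`. Because a larger `A` always depletes the
supply chain, `f` is non-decreasing and the root is unique; it is found
by 52 vectorised bisection steps on `[-Rd - 1, upper]`, resolving `A` to
machine precision (self-consistency residuals below 1e-8 are verified in
the tests). The enzyme-regime upper bound starts at
`min(Vcmax, Vpmax) + 1` and widens to `Vcmax + 1` (a guaranteed bound,
since `Ac < Vcmax - Rd`) if the narrow end does not bracket; the light
regime uses `Jt + 1`. During evaluation `Cm` is floored at 0 and `Cs` at
1e-9; an unfloored `Cm ≤ 0` at the solution is reported as non-physical.
The quadratic for `Jt` is evaluated in the conjugate (cancellation-free)
form, which is exact at `I₂ = 0` and passes smoothly to the rectangular
hyperbola as `θ → 0`.

## 2. Two-stage curve inversion

The measurement protocol mirrors field practice with a portable gas
exchange system: a light-response (Ai) curve at reference CO2 400 ppm
with PAR stepped 2000 → 0 μmol m⁻² s⁻¹, and a CO2-response (ACi) curve at
PAR 1800 with reference CO2 stepped through 200, 100, 50, 250, 400, 650,
800, 1000, 1200, 1400 ppm. Fitting is two-stage: the Ai curve yields
(`Jmax`, `θ`, `PSabs`, `Rd`), which are fed to the ACi stage for
(`Vcmax`, `Vpmax`). `Rd` is anchored by the dark step (`A(0) = -Rd`) and
frozen in the ACi stage; `gm` is fixed (default 1 mol m⁻² s⁻¹ bar⁻¹), not
fitted.

Three practical complications shape the implementation:

* **Crossover on the light curve.** At saturating light a healthy C4 leaf
  becomes enzyme-limited, so fitting the brightest Ai steps with the
  light-limited arm alone biases `Jmax` downward. `fit_ai()` can
  therefore evaluate the full `min(Ac, Aj)` model, given prior values of
  the enzyme parameters; `fit_curves()` supplies a closed-form prior from
  the ACi curve itself (the CO2-saturated plateau approximates
  `Vcmax - Rd`; the lowest-Ci step approximates `Vp - Rm`).
* **Coupling between stages.** The light parameters also shape the ACi
  plateau (which can be electron-transport limited), so after the initial
  two-stage pass `fit_curves()` refines the two parameter *blocks* by
  coordinate descent on the joint sum of squares over both curves,
  accelerated by geometric extrapolation along the step direction. The
  blocks are never merged into a single six-parameter fit. On noise-free
  curves this recovers the generating parameters to well under 0.01%
  across the realistic parameter range.
* **The curvature factor θ.** θ is weakly identified and multi-modal:
  when the enzyme arm clips the bright end of the light curve, little
  curvature information remains. The optimiser therefore profiles θ over
  a grid (re-optimising `Jmax`, `PSabs`, `Rd` at each value) before a
  joint polish, and a `fix_theta` switch reproduces the conventional
  "assume θ = 0.3" treatment, which the pipeline uses by default.
  Under measurement noise a freely fitted θ should not be
  over-interpreted.

Optimisation is bounded Levenberg-Marquardt (`minpack.lm`) from anchored
deterministic starts plus seeded log-uniform restarts (`n_starts`,
default 5); fits are deterministic given (curve, config). Default bounds:
`Vcmax` [5, 150], `Vpmax` [10, 1500], `Jmax` [50, 1000], `Rd` [0, 10],
`θ` [0.05, 0.95], `PSabs` [0.05, 0.9] (all rates in μmol m⁻² s⁻¹).

### Identifiability of Vcmax and outlier exclusion

A plot's data only express `Vcmax` if the CO2 curve is Rubisco-limited
somewhere. Leaves whose `Jmax` is low relative to `Vcmax` are
electron-transport-capped across the entire ACi protocol; their fitted
`Vcmax` is then either arbitrary (it drifts to a bound, where the
enzyme arm has zero gradient) or only a lower bound (colimitation).
`fit_curves()` therefore reports `vcmax_margin`, the gap `Aj - Ac` at the
most CO2-saturated step under the fitted parameters, and the training
pipeline excludes plots whose margin is below 2 μmol m⁻² s⁻¹ — roughly
twice the measurement noise at the plateau — from the `Vcmax` training
set only. This mirrors the field experience that a fraction of CO2
response curves cannot be fitted sensibly.

After fitting, extreme values are excluded per trait using strict
thresholds `Vcmax > 65`, `Vpmax > 750`, `Jmax > 700` μmol m⁻² s⁻¹; each
trait keeps its own valid set.

## 3. Canopy spectra: masking and indices

Plot cubes carry pixel reflectance over 272 bands spanning 395–997 nm
(~2.2 nm sampling). Pixels are classified by NDVI computed from the
nearest bands to 800 and 670 nm; pixels with NDVI strictly greater than
0.5 are averaged per band into the plot reflectance (soil, shadow and
background fall below the threshold). No shadow, sun-angle or BRDF
correction is applied. Nominal index wavelengths resolve to the nearest
sensor band, ties to the lower wavelength — no spectral interpolation,
the minimal assumption for ~2 nm sampling.

The 15-index library (NDVI, OSAVI, NDRE, CVI, PRI, Curvature, Red_edge,
TVI, four band ratios, one normalised difference, and the raw bands r750,
r760) follows the standard published forms; TVI uses the conventional
`0.5 [120 (p750 - p550) - 200 (p670 - p550)]` bracketing (the common
printed variant has unbalanced parentheses). Zero denominators yield a
missing value for that index and plot.

## 4. Trait prediction from spectra

**Approach 1 — PCA-guided stepwise index regression.** The index set is
strongly collinear, so indices are standardised and a PCA ranks them by
squared correlation-scale loading on the first two components; indices
are retained greedily so that no retained pair correlates above 0.9
(|Pearson r|), ties broken lexicographically. The retained subset feeds a
bidirectional stepwise ordinary-least-squares search from the
intercept-only model, scored by AIC (Gaussian likelihood, k = 2),
stopping when no single add/remove lowers AIC.

**Approach 2 — full-spectrum PLSR.** Partial least squares regression
(PLS1, mean-centred; unit-variance scaling is off by default since all
bands share units, with a `scale` switch) on all 272 bands, up to 25
latent variables. The latent-variable count is chosen by the
one-standard-error rule on leave-one-out cross-validated squared
prediction error: the smallest count whose LOOCV MSEP is within one
standard error of the global minimum — a reproducible operationalisation
of "the minimum number that minimises prediction error without
significantly increasing cross-validation error". The plot (not the
genotype) is the observational unit in cross-validation. Reported R² is
the squared Pearson correlation between cross-validated predictions and
observations (`r2_method = "ss"` gives 1 - SSE/SST instead); RMSE is
also expressed as a percent of the trait mean. At full rank PLS1
coincides with ordinary least squares, which the tests verify to 1e-8
against the normal equations; mixOmics serves as an independent
cross-check of the component algebra.

Prediction is affine in the input spectrum (stored centring +
coefficients); models serialise to JSON.

## 5. BLUPs and generalised heritability

Plot-level predictions in a row-column trial are analysed with the mixed
model `y = Xβ + Zu + ε` fitted by REML (`lme4`): fixed intercept and
linear row/column trends; random genotype, row and column effects;
independent residuals. This is a deliberate simplification of the full
field-trial machinery — first-order autoregressive (AR1×AR1) spatial
residual structures and multi-trial variance models are not implemented;
random row/column effects plus fixed trends stand in, and analyses are
per trial. Genotype BLUPs come from the REML fit; prediction-error
variances of all pairwise BLUP differences are computed from the
mixed-model equations assembled at the REML estimates (for more than 200
genotypes, a seeded sample of 5,000 pairs — sampling error on the mean
SED is negligible at that size). Generalised heritability is

`H² = 1 - SED̄² / (2 σ²g)`,

which in the balanced limit coincides with the classical line-mean
heritability `σ²g / (σ²g + σ²e/r)` (verified in simulation). `σ²g = 0`
reports `H² = 0` with a boundary flag; negative values are reported
unclipped but flagged.

## 6. The synthetic-data generator

The generator defines the desk-scale study conditions; all its defaults
are stated here and in `generator_config()`.

* **Genotype truth.** Five traits from a correlated multivariate normal
  (Vcmax–SLN r = 0.6, Jmax–SLN r = 0.5, other pairs 0.2), truncated to
  positive by resampling. Means and spreads are centred on plot-level
  summaries of field-grown sorghum training material: Vcmax 51.1 ± 5.5
  (genetic SD), Vpmax 408 ± 140, Jmax 400 ± 85 μmol m⁻² s⁻¹, SLN
  2.0 ± 0.20 g m⁻², LMA 50 ± 5.5 g m⁻². Plot residual SDs (2.2, 55, 34,
  0.08, 2.2) target a plot-level repeatability near 0.85. Percent leaf N
  is derived so `SLN = (%N/100) × LMA` holds exactly.
* **Layouts.** Partially replicated row-column grids (default: 35% of
  genotypes duplicated), genotype placement randomised under the seed —
  the same shape as a 875-plot / 650-genotype association-panel trial
  when configured so.
* **Curves.** The forward model at the two protocols above, with
  multiplicative Gaussian noise (CV 2%), an additive floor
  (SD 0.2 μmol m⁻² s⁻¹), and intercellular CO2 generated as
  `Ci = Ca × (0.4 + jitter)` with the noise-free backbone computed at the
  jittered Ci, so recorded Ci is internally consistent. Because `Jmax`
  and `Vcmax` are drawn nearly independently, a small fraction of plots
  is electron-transport-capped across the whole ACi protocol — their
  Vcmax is unidentifiable from data, exercising the identifiability
  filter above exactly as low-quality field curves would.
* **Spectra.** Each plot's plant endmember is a smooth basis-function
  spectrum whose features move with the traits, placed where canopy
  reflectance is known to respond: the red absorption trough (~665 nm)
  deepens with SLN (and slightly with Vcmax), the red-edge inflection
  (~715 nm) shifts with SLN, Jmax and Vcmax, the NIR plateau scales with
  LMA and Jmax, the ~955 nm structural dip deepens with LMA, a ~940 nm
  NIR feature follows Vcmax (photosynthetic capacity loads on the red
  edge and the 950–960 nm region, largely beyond the reach of the index
  set, which is what gives the full spectrum its edge over index
  regression), and narrow 760/687 nm features follow Vpmax. Plant pixels (NDVI > 0.6 by construction) mix with a
  spectrally flat soil endmember (reflectance 0.25, small slope,
  NDVI < 0.2) at a configured soil fraction (default 30% of 48 pixels),
  plus band-correlated and independent Gaussian noise. Each trait thus
  has its own spectral direction, so full-spectrum PLSR can succeed but
  latent-variable selection stays meaningful.

**What passing tests do and do not show.** The generator produces
cleaner, better-behaved data than a field trial: its trait–spectrum link
is exact and stationary, its noise is Gaussian and uncorrelated with
traits, and it contains no canopy-structure, phenology, sun-angle or
temperature confounding. Recovery statistics on synthetic data therefore
validate the *machinery* (model inversion, masking, regression,
heritability accounting), not field-level predictive accuracy; on real
canopies, index and PLSR R² should be expected to be substantially
lower, and extrapolation across stages or seasons is untested here.

## 7. Reference problem sizes

The bundled end-to-end demonstration (`run_demo(seed)`) simulates a
training trial of ~150 plots (111 genotypes) with curve pairs and cubes,
trains both approaches for all five traits, extrapolates the PLSR models
to a ~600-plot target trial, and scores BLUP heritability — about five
minutes on one CPU. The Monte-Carlo recovery studies use 200 curve
replicates and 200 simulated trials. These sizes were chosen to make the
full pipeline routinely runnable on a laptop while keeping every stage's
statistics stable; all of them scale with their configs.

## 8. Known limitations

* No AR1×AR1 spatial residual modelling; heritability reflects the
  simplified variance structure.
* θ is not reliably estimable from a 10-step light curve under noise;
  fix it unless the light-limited range is wide.
* `gm` is fixed, not fitted; `Vpmax` estimates absorb any gm
  misspecification.
* Nearest-band lookup (no resampling) ties index values to the sensor
  grid.
* Single-trial heritability only; no multi-trial or genotype-by-trial
  modelling.
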