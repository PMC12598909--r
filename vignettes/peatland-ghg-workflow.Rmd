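---
title: "From chamber traces to greenhouse-gas budgets: methods and design"
author: "peatflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From chamber traces to greenhouse-gas budgets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`peatflux` implements the complete data path of an automatic-chamber
greenhouse-gas experiment on a cultivated, drained Arctic peatland: thirty
transparent 60 × 60 × 60 cm chambers (5 plots along a water-table gradient ×
high/low fertilization subplots × 3 replicate chambers), each closed once
per 8-hour cycle through the May–October snow-free season, with a 1-Hz
analyzer recording CO₂, CH₄ and N₂O mole fractions during each closure.
This vignette explains the models and the design decisions; the README
shows a worked example.

## The synthetic campaign

Because the package is exercised end to end against known ground truth, it
ships a campaign generator (`gen_campaign()`) whose defaults emulate the
field conditions:

* **Radiation** is a deterministic clear-sky solar-elevation curve scaled
  to peak near 300 W m⁻², which at 69.5° N produces continuous daylight
  around the solstice (the polar-day feature that matters for the
  photoperiod analysis). Sampled cloud fields are deliberately omitted:
  the latitude-dependent photoperiod, not weather realism, is the property
  under test.
* **Air temperature** is a seasonal bump peaking near 18 °C in late July
  (≈15 °C June–August mean, subzero by late October) with a diurnal cycle
  and AR(1) weather noise; soil temperatures at 5 and 50 cm are first-order
  low-passes of air temperature with ~3-day and ~20-day memories.
* **Water table level (WTL)** per plot follows a plot-specific summer
  drawdown: the driest plot reaches about −1.6 m, the wettest stays near
  −0.2…−0.65 m, spanning the binning range of the light-response analysis.
* **True fluxes.** CO₂ is a Michaelis–Menten light response (see below)
  whose GPPmax and Rd are suppressed multiplicatively toward wetter water
  tables, Rd with a Q10 temperature response and GPPmax with a post-harvest
  regrowth factor. The suppression rates are chosen so that GPPmax declines
  *faster* than Rd in absolute terms while the ratio Rd/GPPmax still
  shrinks toward wet — this is what makes the light compensation point fall
  from ≈400 W m⁻² to below 100 W m⁻² along the gradient. CH₄ rises exponentially with
  WTL (e-folding depth 0.15 m), making it negligible (≤0.1 mg m⁻² h⁻¹)
  below −0.6 m. N₂O is a small baseline plus post-fertilization exponential
  pulses (7-day decay, halved under the low dosage) amplified when the
  water table sits in the −0.4…−0.3 m window.
* **Default CO₂ constants** (`true_flux_params()`: GPPmax 2600, α 2.0,
  Rd 750 mg CO₂ m⁻² h⁻¹ at 10 °C, suppression rates −0.55/−1.35 m⁻¹) yield
  per-plot seasonal budgets of ≈{20, 14, 9, 5, 2.5} t CO₂ ha⁻¹ — inside the
  −2…27 t ha⁻¹ range such gradients span in the field, with every plot
  clearly away from zero so that relative recovery statements are
  well-posed. A deliberate simplification: the wettest plots remain mild
  CO₂ sources rather than mild sinks; sign realism at the wet end was
  traded for numerically stable relative comparisons.
* **Replicate chambers** sample the same truth surface by default
  (`chamber_sd = 0`); chamber-level heterogeneity that the model predictors
  cannot represent can be injected explicitly when studying the replicate
  variance component.
* **Traces.** Each closure yields a 10-minute 1-Hz ppm series (16-minute
  measurement minus two 3-minute flushes) whose slope exactly inverts the
  flux conversion at the closure's temperature, plus AR(1) noise (0.5 ppm
  marginal SD for CO₂, 0.0015 ppm for CH₄/N₂O — analyzer-scale values, as
  instrument precision is a free parameter) and a stabilization artefact:
  an extra slope `curvature × true slope` decaying with τ = 60 s, which
  bends the first minutes of the trace and makes window selection
  non-trivial. These defaults put the mean selected window near 8 minutes.
* **Seed separation.** `config$seed` fixes the field truth (drivers,
  biomass); the campaign `seed` fixes the observation schedule and trace
  noise, so measurement realisations can be varied over a fixed truth.
  Identical seeds give byte-identical outputs.

What the generator does *not* emulate: real weather (fronts, clouds,
synoptic variability), instrument drift and calibration error, chamber
artefacts beyond the single stabilization transient, lateral carbon export,
and mechanistic soil biogeochemistry. Passing the recovery tests therefore
demonstrates that the *pipeline* is correct and unbiased under known
conditions — not that any particular field dataset would be recovered this
well.

## Flux computation

Fluxes come from linear regressions of concentration against time,
converted with the ideal-gas molar density:

flux = slope · 10⁻⁶ · P/(RT) · M · 10³ · (V/A) · 3600  [mg gas m⁻² h⁻¹]

with V/A equal to the 0.6-m headspace height, M = 44.01 (CO₂ and N₂O) or
16.04 (CH₄) g mol⁻¹, and pressure defaulting to 101325 Pa (site pressure is
not part of the driver set). Emission is positive.

Because automatic chambers overestimate fluxes when the early, unstabilized
part of a closure is included, the fit uses a **dynamic window**: all
candidate windows end at the last sample; the start is scanned forward in
10-s steps, keeping at least 240 s of data; the window with the highest R²
wins and ties go to the longer window. The 240-s minimum keeps every fit
well beyond the short-measurement bias regime; the R² criterion is the
natural reading of "best linear fit", and anchoring the end at the closure
end reflects that the *latter* part of a measurement is the stabilized one.
The search is exact (it equals exhaustive enumeration over the candidate
grid) and implemented with centred cumulative sums, which keeps it both
fast and numerically stable for near-constant traces.

Quality control assigns flag 0 to fits with R² > 0.8 (strictly greater, as
the rule is printed), flag 1 to poorer fits whose flux magnitude lies below
±100 (CO₂), ±0.1 (CH₄) or 0.2 (N₂O) mg m⁻² h⁻¹ — small fluxes near the
detection limit produce noisy traces yet matter for the statistics — and
flag 2 otherwise; flag-2 records are excluded. The N₂O threshold is treated
as an absolute magnitude like the other two.

## Gap-filling

Per-gas random forests (`randomForest`, the canonical implementation of
the `maxnodes` terminal-node cap) with 13 predictors: plot id,
fertilization, global radiation, WTL, wind speed, VPD, day of year,
precipitation, soil temperatures at 5 and 50 cm, air temperature, and days
since harvest/fertilization (event clocks from the most recent preceding
event, 365-day sentinel before a season's first event). Training rows with
|flux| beyond the 95th percentile are duplicated once — the oversampling
multiplicity is otherwise unspecified, and a single duplication is the
mildest choice that still counters the forest's bias against extremes.
CH₄ fluxes above 10 mg m⁻² h⁻¹ are excluded from training but kept for
budgets.

Tuning is a grid search over maxnodes (100–1800 by 100) and mtry (1–12) at
ntree = 600, scored by 10-fold cross-validation with chambers dealt into
folds by a seeded shuffle so no chamber spans folds; the cell with the
lowest RMSE (pooled across folds rather than averaged per fold — both are
defensible; pooled weights every held-out prediction equally) is refit on
all data. The heavy end-to-end checks run a 2 × 2 sub-grid
({600, 1800} × {4, 9}) at ntree = 200 — the tuning machinery is identical
and the full grid remains the default; these sizes are the package's
standard test-problem choice.

Hourly predictions are made for every chamber; hours with an observation
keep the observation. Each of the 600 trees yields its own seasonal total
per chamber (a consistent tree index across hours, rather than resampling
trees per hour — the conservative choice for a sum of correlated hourly
errors), which feeds the bootstrap variance component. Partial dependence
over WTL × 5-cm soil temperature uses standard clamp-and-average over the
empirical distribution of the other predictors; importance is permutation
importance normalised to percentages, as "% explanatory power" does not
name a metric.

## Light response and compensation point

Within 0.3-m WTL bins from −1.5 to 0 m (half-open `[lo, hi)`, each record
binned by its own plot's WTL at measurement time, gap-filled records
excluded), observed CO₂ fluxes are fit to the rectangular hyperbola in the
magnitude parameterization

NEE(Rg) = −(α·Rg·GPPmax)/(α·Rg + GPPmax) + Rd,  α, GPPmax, Rd ≥ 0,

using `minpack.lm::nlsLM` with data-driven starts (Rd from the mean dark
flux, GPPmax from the flux span, α from an initial-slope regression) and a
retry grid. The magnitude parameterization keeps GPPmax positive as
conventionally reported and makes the compensation point

LCP = Rd·GPPmax / (α·(GPPmax − Rd))

algebraically consistent: its defining property is NEE(LCP) = 0, which the
implementation satisfies to numerical precision and which resolves the
typographic ambiguity of the printed formula's denominator grouping. When
GPPmax ≤ Rd the curve never crosses zero and the LCP is undefined (NA).
Light-independent data leave α and GPPmax unidentifiable; the fit then
falls back to the boundary solution GPPmax → 0, Rd = mean flux. Parameter
uncertainties are case-resampling bootstrap SDs over 300 refits; bins with
more than half the replicates failing are flagged unreliable.

## Budgets

Hourly series are summed May 1–Oct 31 and converted with 10⁻⁵ t ha⁻¹ per
(mg m⁻² h⁻¹ · h); missing hours are a hard error — gap-fill first.
CO₂-equivalents use GWP₁₀₀ mass factors 27 (CH₄) and 273 (N₂O). Annual
totals add six off-season months of CO₂ at 1.5 g C m⁻² month⁻¹ and solve
seasonal = 0.85 × annual for CH₄; N₂O has no published off-season rule and
carries over unchanged (conservative). The net carbon balance converts CO₂
and CH₄ to C stoichiometrically and adds 43% of harvested dry biomass;
positive means carbon lost. Subplot budgets are the mean of the three
replicate chambers; replicate variance (across chamber totals) and
bootstrap variance (mean per-chamber variance across tree totals) are
reported side by side.

The photoperiod counterfactual forces Rg to zero between 20:00 and 04:00
local time (no DST adjustment) and re-predicts; both sides of the contrast
use model predictions throughout so the difference isolates the radiation
forcing. Hot moments are records exceeding mean + 4·SD of their (gas ×
subplot) flux distribution — the "4 × SD of mean" phrasing is ambiguous
between this and an absolute 4·SD bound, and mean + 4·SD is the reading
consistent with a skewed emission distribution; their summed share of the
total is reported, undefined when the total is not positive.

## Mixed-effects ANOVA

`fit_with_pruning()` fits response ~ fixed factors + pairwise interactions
with random intercepts for chamber id and measurement date (the repeated-
measures structure), computes Type-III tests with Satterthwaite denominator
degrees of freedom (delegated to `lmerTest`), and removes *all*
non-significant interactions in one step before refitting — matching the
binary keep/drop outcome of the design, rather than stepwise elimination.
Fixed factors with a single level (e.g. year in a one-season run) and
random terms without replication are dropped with a message; when no
usable random term remains — e.g. biomass from a single harvest, one row
per chamber — the model degrades to a fixed-effects fit with Type-III
tests on the residual degrees of freedom. On null
simulations with the campaign's replication structure the per-effect
type-I error sits at ≈5%.

## Numerical choices and limitations

* Window search centres both axes before forming cumulative sums —
  windowed slope/R² are shift-invariant, and centring avoids catastrophic
  cancellation on near-constant ppm series (tiny CH₄/N₂O slopes).
* R² is defined as 0 for zero-variance windows (slope 0), so flat traces
  fall through to the small-flux QC rule rather than erroring.
* Flux conversion is exact for the generator's ideal-gas assumptions; no
  water-vapour dilution correction is applied (the analyzer is assumed to
  report dry mole fractions).
* The light-response fit is per bin with a free α; in sparse or dark-skewed
  bins α and GPPmax trade off, which inflates their individual bootstrap
  SDs while the LCP (a function of all three) stays better determined. In
  bins whose light range never approaches saturation the asymptote GPPmax
  is unbounded (the hyperbola degenerates to a line through α) — such fits
  are recognisable by absurd GPPmax magnitudes and huge SDs, and cross-bin
  parameter comparisons should be restricted to identified bins, as the
  analysis scripts do.
* `hot_moment_fraction` uses equal time weights per record, appropriate for
  a regular measurement cycle.
* Budgets of the synthetic campaign carry a small positive bias inherited
  from residual stabilization curvature in the selected windows (a few
  percent of a typical plot budget, largest in relative terms on the
  wettest, smallest-budget plots) — the same compromise the dynamic window
  makes on real traces.
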