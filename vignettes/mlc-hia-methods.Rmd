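---
title: "Methods: micellar liquid chromatography and logit-linear prediction of intestinal absorption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: micellar liquid chromatography and logit-linear prediction of intestinal absorption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlcHIA)
```

## The problem

Oral drugs must cross the intestinal wall, and the fraction of a dose that
does — percentage human intestinal absorption (%HIA) — is one of the first
properties a candidate compound is screened for. Micellar liquid
chromatography (MLC) offers an inexpensive experimental surrogate: a
surfactant solution above its critical micellar concentration (CMC) is used
as the mobile phase, so a solute's retention reflects how strongly it
partitions into micelles. When the micelles are built from the surfactants of
real intestinal fluid — a mixture of six bile salts and lecithin — the
micelle–water partition coefficient (log P~mw~) measured this way becomes a
biomimetic lipophilicity scale, and together with polar surface area (PSA) it
predicts %HIA well.

mlcHIA implements that pipeline end to end: mobile-phase arithmetic,
retention analysis to log P~mw~, and the logit-linear %HIA regression with
its diagnostic suite, plus seeded simulators so every stage can be tested
against known ground truth without a chromatograph.

## Mixed micellar system arithmetic

The reference mobile phase is a 17 mM bile-salt stock (NaTC 2.71, NaTDC 2.00,
NaDC 2.08, NaC 2.08, NaGC 4.70, NaGDC 3.43 mM) with 0.75 mM lecithin in
0.15 M NaCl at pH 6.5, diluted to test levels with a 2 mM solution of the
same composition so that the monomeric surfactant background stays constant.

Three modelling choices deserve a note:

* **The "total" is the bile-salt total.** The six bile-salt concentrations
  sum to exactly 17.00 mM with lecithin listed separately, so
  `total_concentration()` sums bile salts only; lecithin is stored on the
  mixture but excluded. A user who prefers to count lecithin can add it as a
  component.
* **Mixture CMC is the unweighted mean of the component CMCs** (0.004,
  0.0024, 0.0024, 0.0075, 0.009, 0.0022 M), giving 0.00458 M ≈ 0.0046 M. A
  mole-fraction-weighted mean does not reproduce the reference value, so the
  unweighted mean is the only implemented rule.
* **Micellar concentration** is C~M~ = total − CMC (`micellar_concentration()`),
  the standard definition. The 2 mM diluent is nominally the constant monomer
  background; subtracting 2 mM instead of the CMC is a defensible alternative
  reading, but the package follows the printed definition because it is the
  formula actually stated, and the difference (0.0046 vs 0.002 M) shifts
  every C~M~ by a constant, leaving the binding-fit slope unchanged and only
  rescaling the intercept slightly.

`dilution_fractions()` solves the two-point mixing rule
target = f·stock + (1−f)·diluent; pure diluent is rejected as a test level
because it contains no micelles.

## Retention analysis

For each injection, the retention factor is k′ = (t~R~ − t~0~)/t~0~, with the
dead time t~0~ estimated as the mean of replicate solvent-front times
(`estimate_dead_time()` warns below 10 replicates, the protocol minimum).
Peak times come either from a supplied retention table or from
`detect_apex()`, which smooths the trace with a 5-sample moving average and
takes the global maximum (or, in multi-peak mode, all local maxima more
prominent than 5× the baseline noise SD estimated from the first 5% of
samples — enough to separate a solvent-front peak from the analyte).

For a binding solute the Armstrong–Nome partitioning model gives

$$\frac{1}{k'} = \frac{1}{k'_0} + \frac{K_{AM}}{k'_0}\,C_M,$$

a line in C~M~ whose slope/intercept ratio is the solute–micelle association
constant K~AM~, and log P~mw~ = log₁₀(K~AM~). Replicate k′ values at a level
are averaged **before** the reciprocal is taken; the per-level mean 1/k′ is
the regression observation. Fits are unweighted OLS.

**Convention choice.** The source convention for the reference data prints
the ratio the other way ("log intercept/slope"). Read literally, that ratio
is K~AM~⁻¹ and, over the C~M~ range used (≈0.0004–0.0124 M), would imply
log P~mw~ values far below the 0.93–2.96 range reported for these compounds;
the standard slope/intercept relation is therefore the default. The literal
reading remains available via `convention = "intercept_over_slope"`, and
every `binding_fit` records which convention produced it. No printed
retention times exist to settle the question numerically, which is why the
switch exists.

**Binding classification** uses a two-sided t test on the slope at α = 0.05
(configurable): significantly positive slope → `binding`, significantly
negative → `antibinding` (electrostatically repelled solutes whose retention
rises with micelle concentration), otherwise `none`. The source data are
classified only qualitatively, so a conventional test at the conventional
level is the package's choice. For `antibinding`/`none`, log P~mw~ is `NA`
with a reason rather than an error, so `logpmw_table()` can report a whole
compound panel with per-drug failures isolated.

Degenerate inputs are errors: fewer than 3 distinct levels, non-positive k′,
a non-positive 1/k′ intercept (non-physical), or a flat trace in peak
picking.

## The %HIA regression

%HIA is bounded in [0, 100], so it is linearized with a base-10 logit,

$$\mathrm{logit}(\%HIA) = \log_{10}\frac{\%HIA}{100-\%HIA},$$

which is undefined at 0 and 100: completely (un)absorbed compounds are
excluded from training. Base 10 is used throughout — applying the fitted
reference model to the bundled predictors reproduces the published rounded
predictions (e.g. terbutaline → 34) only under base 10.

`fit_mlr()` is OLS of logit(%HIA) on the chosen predictors (default log P~mw~
and PSA) over the training compounds, reporting:

* coefficients, SEs, t statistics, two-sided p values, and 95% CIs from the
  t distribution with n − p − 1 df;
* standardized coefficients β~j~·sd(x~j~)/sd(y) for comparing predictor
  importance;
* VIF~j~ = 1/(1 − R²~j~) from regressing x~j~ on the other predictors (1 for
  a single predictor);
* R² and adjusted R² on the 0–100% scale, residual SE S in logit units, the
  overall F with its p value, and the PRESS-based predictive R²:
  PRESS = Σ(e~i~/(1 − h~ii~))² from the hat matrix, R²~PRED~ =
  100·(1 − PRESS/SS~tot~). The hat-matrix form is algebraically identical to
  explicitly refitting with each point left out; the test suite verifies the
  identity to 1e−8 on random datasets. A leverage of 1 makes the deleted
  residual undefined and is an error.

`backward_eliminate()` performs the two-phase selection used in this kind of
QSAR modelling: first remove the predictor with the highest VIF while any
exceeds `vif_limit` (default 10 — the usual rule-of-thumb bound, since the
source states only "acceptable limits"), then repeatedly remove the predictor
with the largest p value while it exceeds `alpha_remove` (default 0.05,
matching the significance level reported for the retained terms). The VIF
phase works on the raw predictor matrix so exactly collinear candidates
(VIF = ∞) are screened out before any full fit. The reference study's full
candidate pool (molecular weight, rotatable bonds, molar volume, pK~a~,
solubility, H-bond counts) was never published, so its exact elimination path
cannot be replayed; the procedure is validated on simulated data with known
generating models instead.

Predictions invert the logit, `predict_hia()`, and are rounded half-away-from-
zero when compared against integer-printed tables. `validate_model()` reports
unrounded absolute errors on held-out compounds.

## The bundled reference study

`paper_compounds()` ships the 18-compound table (log P~mw~ measured in the
bile-salt/lecithin system, literature PSA and %HIA). Acetaminophen, ibuprofen
and salicylic acid are the designated validation compounds; acetaminophen's
%HIA of 100 would also trigger the logit exclusion rule, so both reasons
coincide on its role flag. `reproduce_paper()` refits the 15 training
compounds and reports every recomputed statistic side by side with the
published value:

```{r reproduce}
rep <- reproduce_paper()
rep$statistics
```

Agreement is to ≈0.2 percentage points on the R² family and ≈0.002 on the
coefficients; the residual differences are consistent with the bundled
predictors being printed at 2 decimals while the original fit used full-
precision values. One published number does not reproduce: the overall-model
p value of 0.007 is inconsistent with the published F = 38.12 at (2, 12) df
(the F distribution gives ≈4×10⁻⁶); the report carries the computed p value
and a note, rather than matching the printed one.

```{r validate}
rep$validation
```

## Synthetic data: what it emulates, and what it does not

The simulators generate every input with known ground truth:

* `simulate_retention_table()` draws retention times
  t~0~(1 + k′₀/(1 + K~AM~C~M~))(1 + ε), ε ~ N(0, cv²). Noise is
  multiplicative on retention time because chromatographic variability is
  proportional to elution time; the default cv of 1% with 3 replicates per
  level matches routine HPLC repeatability and the triplicate protocol.
  Defaults use 6 levels spanning 5–17 mM total surfactant (converted with the
  0.0046 M CMC) and t~0~ = 1.5 min, a typical dead time for a 15 cm column at
  1.34 mL/min. Antibinding is simulated with negative K~AM~, valid while
  K~AM~C~M~ > −1.
* `simulate_chromatogram()` adds trace realism: Gaussian analyte and
  solvent-front peaks, linear baseline drift and additive detector noise.
* `simulate_compound_table()` draws predictors uniformly over ranges covering
  the reference compounds (log P~mw~ 0.9–3.0, PSA 37–89 Å²) and generates
  logit(%HIA) from the reference coefficients with noise SD 0.247 — the
  reference model's residual SE — then back-transforms. Records landing on
  the 0/100 boundary at double precision are redrawn.

All simulators take integer seeds, restore the global RNG state, and are
byte-for-byte reproducible in exported CSV. What they do **not** emulate:
peak tailing, pump pulsation, inter-day drift, correlated predictor
distributions, or measurement error in PSA. Passing round-trip tests
therefore shows the estimators are correct under the stated generating laws,
not that real chromatograms are this clean.

## Problem sizes and numerical choices

The test suite uses deliberately modest problem sizes — 200-replicate
recovery studies, 50-dataset PRESS identities, n ≤ 200 regressions — chosen
as the smallest sizes at which the distributional claims (95% recovery rate,
2% mean bias) are stable; the whole suite runs in seconds. Ties in backward
elimination resolve to the first maximum (`which.max`). Exact-fit data (zero
residual variance) are a designed use case for round-trip tests, so the
"essentially perfect fit" warning from `summary.lm` is muffled — and only
that warning. Seeds embedded in tests are arbitrary fixed integers.

## Limitations

* Table-derived log P~mw~ values are inputs, not recomputable: the raw
  retention times behind them were never published, so the retention stage is
  validated by simulation round trips, not against the reference compounds.
* Only the linear 1/k′ treatment is implemented; Foley-type variants are out
  of scope.
* Weighted or robust regression, applicability-domain estimation and
  descriptor calculation from structure are out of scope; predictors are
  taken as given.
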