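---
title: "Growth-curve processing and fitness-component extraction with odgrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-curve processing and fitness-component extraction with odgrowth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odgrowth)
```

## The problem

High-throughput microbial phenomics screens record optical density (OD)
of hundreds of cultures over days, in instruments such as the Bioscreen
C. Downstream analysis wants three scalar fitness components per
culture — the **lag** (hours before net population growth starts), the
**doubling time** during maximal exponential growth, and the
**efficiency** (total population-size gain at stationary phase, the
yield of the limiting resource). Raw OD traces are not directly usable
for this: they carry single-point and multi-point spikes, sustained
signal collapses from bubbles or wall adhesion, high-frequency noise,
and a systematic sublinear response of OD to cell density above roughly
OD 0.3. `odgrowth` implements the whole path from a raw plate-reader
export to calibrated curves, fitness components, and per-curve quality
scores, with a synthetic-curve generator as a ground-truth instrument
stand-in.

## The processing model

Each well's series passes, in order, through:

1. **Median filter**, window 3, endpoint-clone padding. Removes isolated
   spikes exactly on flat regions; on a steep stretch it substitutes a
   neighbouring reading. A 3-point window cannot remove "wide spikes"
   covering 2+ consecutive points — by design, the cheap filter handles
   the dominant artefact class.
2. **Mean filter**, window 3, same padding. Damps residual
   high-frequency noise. The cloned-endpoint padding slightly bends the
   two boundary values of a sloped series (by up to one-third of a local
   increment per pass); interior points of linear stretches are
   preserved exactly. We accept this bias because the extractors below
   never rely on the two boundary points alone.
3. **Monotonicity filter** (optional, default on): a running maximum.
   True batch-growth population curves are non-decreasing; sustained
   drops are artefacts. The total correction applied is retained — it
   *is* quality index 4.
4. **Blank subtraction and calibration.** The user-supplied blank (a
   single scalar per run; backgrounds are assumed position-independent)
   is subtracted, negative results are clamped to zero, and the cubic
   response model
   $$y = x + c\,x^3$$
   maps blank-corrected OD $x$ to a population-size estimate $y$. $c$ is
   an empirical species-and-instrument constant; five presets ship with
   the package (`calibration_preset(NULL)`), and `fit_calibration()`
   estimates $c$ from a dilution series by the closed-form least-squares
   solution $\hat c = \sum x^3(y-x) / \sum x^6$ (the model is linear in
   $c$, so no iterative fitting is needed; a negative estimate is
   clamped to 0). Clamping negative blank-corrected OD before cubing is
   our choice: the cubic would otherwise emit negative "population
   sizes".

## Fitness-component extraction

All log-scale work uses log10. Values ≤ 0 after calibration are
replaced by the smallest positive value of the series before logging;
a series with no positive values yields no trait estimates.

**Lag.** On the log10 curve, the initial level $y_0$ is the mean of the
first five estimates. Slopes come from 8-point sliding regressions
(regressions always use the actual time values, so irregular sampling
is handled). Each window extrapolates to an intercept time
$t^* = t_{mid} - (y_{mid}-y_0)/k$, and the lag is the mean of the two
largest intercepts, clamped at ≥ 0. Two numerical guards are ours:
windows must have $k \ge \max(0.5\,k_{max}, 0.01)$ — near-flat windows
would otherwise extrapolate to unbounded intercepts — and "two largest
intercepts" is read literally as the largest intercept *times* (the
alternative reading, intercepts of the two steepest windows, is
available as `lag_intercept_rule = "steepest_slopes"`). On an ideal
log-linear curve both readings coincide with the true lag. Two
consequences worth knowing: a curve that grows from $t = 0$ shows an
apparent lag of up to two sampling intervals (the $y_0$ level sits at
the centroid of the first five points), and on diauxic curves whose
second phase is faster than half the maximal slope the literal reading
drifts toward the second phase — the `steepest_slopes` rule does not.

**Doubling time, default method.** Points before 3 h are excluded
(early slopes can reflect cell-size recovery from starvation, not
division). 3-point window slopes of the log10 curve are ranked, the two
highest discarded as potential residual artefacts, and the mean
$\bar x$ of the next five is converted as
$DT = \log_{10}(2)/\bar x$ hours. The conversion formula is implied
rather than stated by the convention that slopes are log10 per hour.

**Doubling time, regression method.** Five-point sliding regressions;
the single highest slope is converted to a doubling time. The same 3-h
exclusion is applied (our choice, for comparability between methods).
This estimator averages over more of the curve per window and is less
inflated by sparse sampling and noise — the package's
sampling-interval sensitivity check reproduces that ordering.

**Efficiency.** $\bar x_{top}$ (mean of the six highest calibrated
values) minus $\bar x_{base}$ (mean of the two smallest). If
$sd(\text{top six})/\bar x_{top} > 0.02$ the curve has not plausibly
reached stationary phase and no estimate is made — undefined is
reported, never zero. Calibrated values are used throughout: the
calibration correction matters most near the plateau, exactly where
efficiency is read.

## Quality indices and flagging

Quality scoring works on the **raw** series, so it sees what the
filters would remove. Growth-phase windows are 5-point regressions with
slope > 0.07 raw-OD/h (the threshold's units are a package choice, made
configurable via `slope_threshold`, since plausible alternatives exist;
per-hour raw OD keeps it sampling-interval invariant).

* **QI1, overall noisiness** = 1 − mean $r^2$ over qualifying windows.
* **QI2, local noisiness** = 1 − mean of the three worst $r^2$.
* **QI3, number of spikes** = count of qualifying windows with
  $r^2 < 0.5$ (QI3 shares QI2's window set).
* **QI4, curve collapses** = total monotonicity-filter correction on the
  smoothed series; positive exactly when that series is non-monotone.

A window with zero variance is scored $r^2 = 1$ (a flat line fits it
perfectly); this avoids 0/0 and keeps flat plateaus from polluting the
noise indices. Curves with no qualifying window get undefined QI1/QI2
and a *no-growth advisory*, not a quality flag.

Flagging thresholds are empirical $(1-f)$ quantiles (linear
interpolation between order statistics — pinned so flag counts are
reproducible) of each index over a reference batch, with $f = 0.05$ by
default, the level at which false positives and false negatives balance
best. The reference distribution is computed from the current batch or
from a user-supplied index file (`qi.reference_file`); a sensible
reference is large and predominantly clean, as routine lab batches are.
An index flags a curve when its value strictly exceeds the cutoff;
flagged curves are meant for operator inspection, never automatic
rejection.

## The synthetic generator

`curve_spec()`/`generate_curve()` build the true curve on the log10
population scale: flat at `baseline` through the lag, log-linear growth
at $\log_{10}(2)/DT$, saturating at `baseline + efficiency`. The two
joins are smoothed — softplus at the lag corner (sharpness
`lag_sharpness`, default 10 h⁻¹) and a soft minimum at saturation
(`sat_sharpness`, default 60 per log10 unit) — so the ideal piecewise
limit is reachable with `Inf` sharpness for exact tests; the defaults
give transition scales of ~0.1 h and ~0.02 log units, on the sharp end
of what real cultures show. The curve is mapped to instrument OD by
*inverting* the calibration function (Cardano closed form plus one
Newton polish), the blank is added, and Gaussian noise plus artefacts
are injected on the OD scale, where instrument noise lives: isolated
spikes, wide spikes, sustained collapses, and (on the population scale)
a second, diauxic-like growth phase.

`generate_benchmark()` emulates paired validation sets: clean curves
cycle a 3×3×3 grid of lag {2, 5, 10} h × doubling time {1.5, 3, 6} h ×
efficiency {0.5, 1.0, 1.5} with ±5–10 % jitter, instrument-level noise
(sd 0.002 OD), and a slower second phase (3× the first-phase doubling
time, gain 0.3) on every seventh curve; corrupted curves add one or two
artefact types drawn uniformly, with amplitudes chosen to represent
seriously compromised data (spikes 0.15–0.6 OD, collapses losing
40–90 % of signal, noise sd 0.03–0.08 OD). What the generator does
*not* emulate: plate-position and edge effects, signal drift,
evaporation, heteroscedastic noise, or condensation — passing the
benchmark shows the estimators and indices behave as designed on the
stated curve model, not that any real dataset is problem-free.

## Problem sizes and numerical choices

The validation battery (tests and `scripts/acceptance.R`) uses: 1,000
random series for exact filter-vs-brute-force comparison; the 27-point
noiseless grid at 20-min sampling over 72 h for trait recovery (lag
within one sampling interval, doubling time within 2 %, efficiency
within 1 %); a 600-curve reference batch (95 % clean) for thresholds
and a 100 + 100 clean/corrupt set for flag rates; and sampling
intervals {20, 40, 60, 120, 240} min on a soft logistic for the
rate-method sensitivity ordering. These sizes give stable quantiles and
run in seconds on one CPU.

Under instrument-level noise the max-slope-style rate estimators carry
an upward rate bias on slow growers: the monotonicity filter turns
near-flat noisy stretches into staircases whose jump windows inflate
log-slopes at low population sizes. Both rate methods are affected, the
default method more; agreement between the two is therefore assessed on
the slope scale (where both estimators operate, observed $r^2 \approx
0.997$ on the clean benchmark) rather than on the reciprocal
doubling-time scale, which amplifies exactly this slow-grower spread.

Other pinned choices: doubling times are reported only for positive
trimmed-mean (or maximum) slopes, otherwise undefined; the calibration
inversion is exact to ~1e-15 over the working range; exports print six
significant digits (instrument precision); Bioscreen `hh:mm:ss` stamps
may exceed 24 h, decimal-hour time columns are auto-detected, and
decimal commas are normalised in tab-delimited files.

## A worked example

```{r example}
bench <- generate_benchmark(n_clean = 30, n_corrupt = 5, seed = 42)
fit <- growth_fit(bench$run, calibration = "S. cerevisiae")
fit
head(coef(fit), 4)
subset(fit$table, flags != "", select = c(well, qi1, qi3, qi4, flags))
```

## Known limitations

* No parametric growth-model fitting (logistic/Gompertz/Baranyi), no
  area-under-curve traits, no diauxic-phase segmentation; the extractors
  summarise the curve, they do not model it.
* The lag estimator's literal "two largest intercepts" rule is biased on
  multimodal curves with a moderately slower second phase (see above).
* Quality thresholds are only as good as the reference batch; a batch
  dominated by bad curves makes every index look normal.
* A single scalar blank per run; no per-well or time-varying background.
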