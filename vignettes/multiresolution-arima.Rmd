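---
title: "Multi-resolution ARIMA forecasting of cerebral physiologic signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-resolution ARIMA forecasting of cerebral physiologic signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocast)
library(dplyr)
```

## The problem

Continuous neuromonitoring of patients with traumatic brain injury produces
high-frequency arterial blood pressure (ABP), intracranial pressure (ICP)
and, in a subset of patients, brain tissue oxygen (PbtO~2~) waveforms.
Bedside analytics condense these into minute-by-minute summaries: mean
pressures (MAP, ICP, CPP = MAP − ICP), the cardiac pulse amplitude of ICP
(AMP), and cerebrovascular reactivity (CVR) indices — PRx, PAx, RAC and RAP
— computed as moving Pearson correlations between slow-wave components of
the pressures. A natural question for forecasting-based decision support is
how far these signals can be predicted ahead, and how that ability degrades
when the series is averaged to coarser and coarser temporal resolutions
(1 min up to 24 h). `neurocast` implements that experiment end to end:
signal synthesis, derivation, resolution reduction, ARIMA modelling, and
evaluation under three time-series cross-validation schemes.

Real multi-centre TBI recordings are sensitive clinical data and are not
shipped with the package. The synthetic cohort module generates records
with the statistical structure the analysis assumes, so that every stage is
testable against known ground truth; user-supplied minute CSVs in the
documented schema drop into the same pipeline.

## The signal model of the synthetic cohort

`sim_config()` builds each channel additively:

* **ABP** — baseline + minute-scale random-walk drift + three slow
  vasogenic sinusoids (0.005–0.05 Hz band) + a respiratory oscillation
  (0.25 Hz) + a cardiac pulse (fundamental plus two harmonics) + white
  noise.
* **ICP** — baseline + drift + *g* × (MAP slow-wave component) + an
  independent ICP slow wave + a cardiac pulse whose amplitude is modulated
  by the normalised slow-wave level + noise. The signed gain *g* is the
  autoregulation coupling: *g* > 0 emulates impaired reactivity (pressure
  passively transmitted, PRx > 0), *g* < 0 intact counter-regulation
  (PRx < 0).
* **PbtO~2~** — baseline + drift + gain × (CPP slow-wave component lagged
  20 s) + noise; the lag makes the channel predictable but imperfectly so.

Defaults: MAP 87 / ICP 12 mmHg baselines (typical adult TBI cohort
medians), cardiac frequency 1.2 Hz, slow waves of 3/2/1 mmHg at 0.0083,
0.0222 and 0.0455 Hz with seeded random phases, 1 mmHg white noise, and
random-walk drifts of 0.3 (MAP), 0.15 (ICP) and 0.1 (PbtO~2~) mmHg per
√minute. The drift term matters: without it, hour-scale averages of purely
periodic components are nearly constant and coarse-resolution forecasting
would be trivially easy, the opposite of what real recordings show. The
slow-wave model is a fixed sum of sinusoids rather than filtered noise so
that windowed-correlation predictions stay analytically tractable; the
cardiac frequency is constrained to multiples of 0.1 Hz so a 10-s frame
holds a whole number of cycles and spectral amplitude estimates are
leakage-free.

What the generator does **not** emulate: realistic ICP pulse morphology
(only the fundamental-plus-harmonic amplitude structure AMP needs),
physiologic transfer lags between MAP and ICP slow waves, artifacts, and
non-stationary regime changes. Tests passing on this cohort therefore
establish that the pipeline recovers imposed structure correctly — not that
any clinical performance figure transfers to real data.

## Derivation of the minute record

`derive_minute_record()` chains the standard steps: 10-s non-overlapping
block means of each channel (a frame is valid when at least 50% of its
samples are unmasked — a majority rule, since short dropouts then leave the
mean unbiased); AMP per fully observed 10-s ICP frame via a periodic Hann
window, DFT, and the maximum-magnitude bin in the cardiac band
0.67–3.0 Hz, rescaled by the window's coherent gain; CPP = MAP − ICP; and
the four CVR indices as Pearson correlations over trailing windows of 30
frames (5 min) updated every minute. Windows are trailing (causal) and
demand full validity — in a forecasting context a centred window would leak
future information. Minute means use the 6 frames of the minute and
require at least 4 valid frames.

Two conventions are deliberate readings of under-specified practice: AMP
takes the *peak* cardiac-band bin (the fundamental), and index windows are
trailing rather than centred. Both are documented here because alternative
readings exist in deployed software.

## Resolution reduction, gaps, differencing

`reduce_resolution()` averages non-overlapping windows over the ladder
{1, 5, 10, 15, 30, 60, 120, 180, 240, 300, 360, 720, 1440} minutes,
requiring ≥ 50% of a window's minutes present. `handle_gaps()` applies the
missing-data rule at the working resolution: runs of 1–4 missing points are
linearly interpolated between flanks; runs of ≥ 5 are removed, splitting
the series into segments (a run of exactly five is removed — the
conservative reading of a rule stated only for "fewer than five" and "more
than five"). Leading/trailing missing runs are trimmed since no flank
exists to interpolate from. Modelling proceeds on the longest contiguous
segment; fabricating continuity across removed spans would distort the
autocorrelation structure the models estimate.

`difference()` stores initial values so inversion is exact to machine
precision — forecasts on the differenced scale are integrated back through
the same mechanism. Stationarity diagnostics use a hand-implemented ADF
test (constant, no trend; lag order by AIC over a common sample;
MacKinnon-style 5% critical values) and the level-stationary KPSS test
(Bartlett bandwidth ⌊4(n/100)^¼⌋, 5% critical value 0.463), matching the
specification that motivates first-order differencing.

## ARIMA by conditional sum of squares

The core model for the differenced series is

$$\Delta^d y_t = c + \sum_{i=1}^{p} \phi_i y_{t-i}
  + \sum_{j=1}^{q} \theta_j e_{t-j} + e_t,$$

estimated by conditional sum of squares: residuals are generated by the
recursion with zero initialisation for $t \le \max(p,q)$ and the Gaussian
likelihood is maximised over $(c, \phi, \theta)$ with $\sigma^2$
concentrated out. CSS was chosen over exact state-space likelihood because
it is fully specified by the recursion above, fast enough for grid
searches, and directly testable against closed forms; an exact-MLE mode
would be a natural extension. Three numerical choices matter:

* **Admissibility.** Stationarity and invertibility are enforced through a
  partial-autocorrelation transform (tanh of unconstrained reals mapped
  through the Durbin–Levinson recursion), so every optimiser iterate is a
  valid model. Convergence tolerance is 1e-8 on the objective.
* **Comparable AIC.** σ² is estimated from the $n - \max(p,q)$ conditional
  residuals, but the reported log-likelihood is scaled to the full
  differenced length. Without this, models with larger $\max(p,q)$ enjoy a
  spurious likelihood advantage (they condition away more points) and the
  grid search systematically overfits. AIC counts $k = p + q + 2$
  parameters.
* **Degenerate fits.** When differencing reduces a series to (numerically)
  zero variance — an exact polynomial trend — the deterministic model with
  zero coefficients is returned directly with a floored σ², so such series
  are forecast exactly rather than failing.

The constant is estimated for $d = 0$ and fixed to zero for $d \ge 1$ (a
constant under differencing implies a deterministic polynomial trend the
analysis never invokes). The order grid is $p \in [1,10]$, $d \in [0,2]$,
$q \in [0,10]$; the floor at $p = 1$ is intentional fidelity to the
analysis protocol even though $p = 0$ models exist. Ties in AIC break
toward smaller $p + q$, then smaller $q$, then smaller $d$.

One property of minimum-AIC selection is worth stating plainly: on pure
white noise, with twelve candidate orders, the smallest admissible model
wins only a minority of draws — overfitting by a few spurious parameters is
intrinsic to AIC, and an exact-MLE reference implementation reproduces the
same rate. The package's tests therefore check selection *consistency* on
structured data (AR(2) input selects $p \ge 2$) and oracle-equivalence on
noise, not an unattainable parsimony rate.

Forecasts follow the conditional-expectation recursion on the differenced
scale and are integrated back; the $h$-step standard error is
$\sigma\sqrt{\sum_{j<h}\psi_j^2}$ with ψ weights cumulated $d$ times to the
original scale, and prediction intervals are Gaussian
(point ∓ $z_{(1+\text{level})/2}$ · se). The interval construction in the
underlying protocol is unspecified beyond "confidence intervals"; the
Gaussian innovation form is the standard reading.

## Cross-validation schemes

Three split plans preserve chronology (`one_step_folds()`,
`blocked_folds()`, `tss_folds()`), all with $n = 5$ folds by default:

* **one_step** — expanding window; the final half of the series is
  evaluated point by point, each with all prior observations as training
  data. The five "splits" are reporting folds grouping consecutive test
  points; the order is re-selected per fold and coefficients are
  re-estimated at every step. This realises "the training set is updated
  to include the newly observed data" while keeping the AIC grid search
  tractable.
* **blocked** — five contiguous blocks; within each block 70% trains, a
  2-point gap is discarded against leakage, the remainder tests. The
  70%/gap-2 proportions are schematic in the source protocol and are
  exposed as configuration.
* **tss** — the series is divided into $n+1$ sequential partitions; fold
  $k$ trains on the first $k$ and tests on the next.

Interval prediction (horizon 5, 95% by default) runs under one_step — the
evaluation region is covered by non-overlapping 5-step blocks, the window
advancing by the horizon so every point is evaluated exactly once — and
under tss, forecasting the head of each test partition. The blocked scheme
is restricted to point prediction; its fixed non-overlapping blocks do not
support stable interval estimation, and `run_interval_cv()` rejects it
with exactly that message. Prediction failures degrade to missing entries
rather than aborting a patient, as a cohort-scale batch run requires.

## Metrics and aggregation

MAE, RMSE and R² follow their defining formulas (R² may be negative; it is
missing when the actuals have zero variance). CI spread is the mean width
of the prediction interval (a median variant is available). Per-patient
metric rows aggregate across patients by mean and SD (n − 1 denominator;
SD over a single contributing patient is reported as 0), with missing
metrics excluded, never imputed. `summary_table()` and
`plot_metric_heatmap()` lay the cohort means out as signals × resolutions
tables with R² as the cell value and RMSE as companion.

## Problem sizes and benchmark defaults

The pipeline skips any (signal, resolution) cell whose longest contiguous
segment is shorter than `min_points` (default 30) — at 24-h resolution a
fortnight of data yields barely a dozen points and fitted models are
dominated by noise, so skipping is surfaced in the `skipped` table rather
than silent. For the package's own end-to-end checks we run 5 synthetic
patients × 12 h at resolutions {1, 5, 15, 60} min with a reduced order
grid (p ≤ 2, d ≤ 1, q ≤ 1) and `min_points = 8`, so the 60-min cells
(12 points at 12 h) materialise; the recovery, calibration and coverage
studies use n = 1000–2000 with 20–50 Monte-Carlo replicates. These sizes
were chosen to exercise every code path at desk scale while keeping the
full suite re-runnable in minutes; they are configuration, not limits of
the implementation.

## Known limitations

* CSS conditioning discards $\max(p,q)$ points per fit; on very short
  segments (coarse resolutions) this measurably shrinks the usable sample.
* Gaussian prediction intervals understate uncertainty when innovations
  are heavy-tailed; bootstrap intervals are out of scope.
* The blocked scheme's within-block forecasting anchors on the training
  block and earlier test observations; the discarded gap introduces a
  small step in the information set that mildly disadvantages high-order
  MA terms.
* Seasonal structure (circadian rhythms) is neither simulated nor
  modelled; the order grid contains no seasonal terms.

## A worked example

```{r example, eval = FALSE}
rec <- generate_patient_waveforms(
  sim_config(duration = 120, autoregulation_gain = 1, seed = 42))
minutes <- derive_minute_record(rec)
mean(minutes$PRx, na.rm = TRUE) # ~0.9: impaired reactivity recovered

icp5 <- reduce_resolution(minutes$ICP, 5, "ICP") |>
  handle_gaps() |>
  longest_segment()
sel <- select_order(icp5, p_range = 1:3, d_range = 0:1, q_range = 0:1)
arima_forecast(sel$fit, horizon = 5)
```
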