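---
title: "Modelling heat stress and milk production: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heat stress and milk production: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and of the
design decisions behind them. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The modelling problem

On an automated-milking-system (AMS) farm, cows present voluntarily
for milking and the robot records, per cow and day: lactation days and
number, milking frequency, milk yield (kg/day), protein and fat (%),
programmed and consumed concentrate feed (kg/day), and liveweight
(kg). A weather station supplies temperature, humidity, rainfall, wind
and (optionally) pressure. The task is to predict the four production
targets from 21 daily inputs — the five weather maxima, dewpoint,
wet-bulb, nine THI variants, and five management variables — and to
use the fitted model inside an automated drafting gate that routes
heat-stressed cows to sprinkler cooling.

## Psychrometrics and the THI family

Dewpoint uses the Magnus formula with constants 17.67 and 243.5 °C;
at RH = 100 % it reduces exactly to the identity. Humidity at or
below 0 % is a domain error (the logarithm is undefined), never a
silently clipped value.

Wet-bulb temperature is the root of the psychrometer balance
`e(Tdp) = es(Twet) - A * P * (T - Twet)`, solved by bisection on
`[Tdp, T]`. Design choices, since only the variables and the solver
family are conventionally fixed:

* saturation vapour pressure in the Magnus form consistent with the
  dewpoint constants (reference 6.112 hPa), so the two derivations
  cannot disagree at saturation;
* psychrometer coefficient A = 6.6×10⁻⁴ K⁻¹, the unventilated
  standard;
* default pressure 101.325 kPa (one atmosphere), used when a weather
  file carries no pressure column;
* absolute tolerance 0.001 °C with an iteration cap of 100. The
  bracket is at most ~50 °C wide, so bisection needs ~16 halvings;
  the tolerance is far below sensor precision at negligible cost. The
  bracket is guaranteed: the balance is negative at `Tdp` and
  non-negative at `T`, so `Tdp <= Twet <= T` holds by construction.

The nine THI variants are evaluated with strict left-to-right
grouping. That grouping makes `THI1 - THI4` identically 6.4
(`0.4·1.8 = 0.72` cancels the paired term), a convenient algebraic
fingerprint the tests assert everywhere. Variant 5 circulates in two
readings: the package's default evaluates the linear term as
`(1.8 + T - 26)`, and `thi5_dialect = "corrected"` evaluates
`(1.8*T - 26)` as in most of the index literature. Summary statistics
cannot discriminate the two (the multiplier `0.55 - 0.0055*RH` is
near zero in humid conditions), so both are provided and neither is
asserted as canonical.

## The synthetic farm

Real AMS records are proprietary, so the package ships a seeded
generator whose *response model is known*, making parameter recovery
testable. What it emulates:

* **Weather**: daily-maximum temperature as an annual cosine (mean
  21 °C, amplitude 9.5 °C, peak mid-January — a Southern-Hemisphere
  warm-temperate site) plus an AR(1) residual (coefficient 0.7,
  innovation sd 3.5 °C); humidity with a winter-peaking cycle coupled
  negatively to the temperature anomaly; Bernoulli–gamma rainfall
  (wet-day probability 0.35); gamma wind. Values are kept within
  physical bounds (T in [−5, 48] °C, RH in (5, 100]). These defaults
  put winter mean THI₉ near the high 40s and summer means in the
  high 70s to mid 80s, with yearly target means inside the published
  envelopes the tests check.
* **Herd**: heat-tolerance breeding values uniform on [93, 112] —
  genomic scores centred at 100, where 93 reads as 7 % less and 110
  as 10 % more heat tolerant than average; parities 1–8; staggered
  calving; about 10 % extended-lactation "carryover" cows (>600-day
  lactations), exercising that input range.
* **Response**: latent yield is a Wood curve `A·t^b·e^(−c·t)`
  (A = 14, b = 0.25, c = 0.0035; peak ≈ 32 kg/day near day 70)
  scaled by parity, liveweight `(lw/660)^0.7`, milking frequency
  `(freq/2.4)^0.15`, a small log-normal cow effect (sd 0.03), and the
  heat decrement `1 − k_y·s(bv)·max(0, THI₉ − 72)` with k_y = 0.008.
  The threshold 72 is the conventional comfort boundary and sits
  between typical winter and summer THI means. Protein has a
  winter-peaking cycle and a heat penalty; fat is diluted by yield;
  intake is the programmed feed capped by a heat-depressed appetite
  capacity (k_i = 0.02). Observed targets add Gaussian noise
  (sd 2.5 kg, 0.28 %, 0.55 %, 0.9 kg) and clip at zero. Zero-frequency
  days (an unmilked cow) force zero yield and zero intake; protein and
  fat retain their latent composition values, read as udder-milk
  composition rather than a sale measurement.

What it deliberately does **not** emulate: individual pasture intake
(not measurable under commercial grazing), disease and mastitis
dynamics, within-day milking-session structure, carry-over
physiological effects of past heat on future yield, and any effect of
cooling on subsequent production. Passing recovery tests on this
generator therefore demonstrates that the pipeline can recover a
response *of this structure* from realistic noise — not that the real
farm obeys this structure.

All magnitudes are module defaults exposed in `weather_sim_params()`
and `response_params()`, not claims about any real farm.

## Dataset conventions

* **Daily aggregation**: temperature, humidity and wind speed are
  daily maxima; rainfall is the final value of the day's running
  total. A "maximum" of wind-direction degrees is physically
  meaningless, so the default takes the direction observed at the
  maximum wind speed (ties: earliest record); the literal reading
  remains available as `winddir_daily = "literal-max"`.
* **Normalisation**: min–max to [−1, 1], fitted on the training rows
  only so no test information leaks into the mapping; test values
  outside the fitted range map outside [−1, 1] and are not clipped.
  `normalize_on = "all"` reproduces the whole-data-set reading.
* **Split**: uniform random over cow-days (not cows), with
  `round(fraction * n)` training rows — the rounding rule the
  published partition counts pin down exactly (29,114 → 20,380/8,734;
  166,459 → 116,521/49,938). Pooled observation counts are rows × 4
  targets.
* **Missing data**: drop-row, counted, no imputation. Zero milking
  frequency is a retained, legitimate value.

## The Bayesian-regularized network

One network serves all four targets: 21 inputs, ten tan-sigmoid
hidden units, four linear outputs (264 weights). Training is
Levenberg–Marquardt on `F = beta*E_D + alpha*E_W`:

* step `dw = -(beta*J'J + (alpha+mu)*I)^(-1) (beta*J'e + alpha*w)`;
  `mu` starts at 0.005, ×10 on a rejected step, ×0.1 after an
  accepted one, cap 10¹⁰;
* the Jacobian is exact per-sample backpropagation, accumulated
  chunk-wise as `J'J` and `J'e` so the full `(4n) × 264` Jacobian is
  never materialised; chunk size only trades memory, never results;
* after each accepted step, the MacKay evidence updates:
  `gamma = N_w - alpha*tr(H^(-1))` with `H = beta*J'J + alpha*I`
  (Gauss–Newton Hessian at the accepted step's linearisation point),
  then `alpha = gamma/(2*E_W)`, `beta = (N_D - gamma)/(2*E_D)`;
  `alpha` starts at 0 and `beta` at 1, so the first epoch is plain
  LM and the first update gives `gamma = N_w`;
* initialisation is Nguyen–Widrow over the [−1, 1] cube, seeded;
* stopping: epoch cap, gradient infinity-norm below 10⁻⁷, or no
  improving step below the `mu` cap. There is no early-stopping
  validation set: regularization replaces it, mirroring the plain
  70/30 split.

Within an epoch the acceptance test `F_try < F` is made under that
epoch's `alpha`/`beta`, and the history records both sides, so
"accepted steps never increase F" is checkable even though `F` is
re-weighted between epochs.

A property worth spelling out: on *noiseless* data the evidence
update drives `beta` to infinity as `E_D → 0`, `H` is dominated by
`beta*J'J`, and `gamma` rises toward `N_w` — with no noise, every
parameter direction the data touch is well determined. The
capacity-pruning behaviour of `gamma` (its value tracking the
problem's effective complexity rather than the network's size) is
therefore demonstrated in the tests on a *noisy* linear problem,
where widening the network from 8 to 15 hidden units leaves `gamma`
essentially unchanged; the noiseless problem is instead the accuracy
benchmark (test MSE < 10⁻⁴).

## Evaluation conventions

* Metrics pool the four normalized targets into a single
  (prediction, observation) cloud: one R, one slope, one MSE per
  stage, matching the single-value-per-stage reporting convention;
  per-target normalized R and original-unit RMSE are emitted as
  supplementary output.
* The slope `b` is of the fit `obs = b*pred + a`.
* "95 % bounds" is read as the *prediction* interval of that fit:
  only prediction intervals, which scale with the residual sd, yield
  per-observation outlier counts of the published kind (confidence
  intervals of the mean response shrink with n and would flag most
  points at these sample sizes). `bounds = "confidence"` preserves
  the alternative. Under well-specified Gaussian residuals the
  outlier fraction converges to ≈5 %, which the tests assert by
  Monte Carlo at n = 10⁵.
* Seasons are meteorological, with December assigned to the
  following year's summer (Southern Hemisphere default; the
  hemisphere flag relabels months without changing any mean).

## Drafting logic

A cow is flagged heat-stressed when the day's THI₉ exceeds the
threshold **and** any model-predicted target falls below its floor —
the conjunction honours both the environmental trigger and the
production thresholds; a disjunction mode is available. The state
machine is `NORMAL → STRESSED_DAY1 → STRESSED_PERSISTENT`, with
`COOLING` on the first flagged day, `COOLING_AND_MILK` from the
second consecutive flagged day (milked despite cooling, to avoid
mastitis), and recovery to `NORMAL` on any unflagged day. Whether a
day-1 cooled cow should also be milked is genuinely open; the default
defers milking on day 1 and the decision log records enough state to
implement either farm policy.

One subtlety the tests encode: raising the THI threshold shrinks the
set of flagged days, but can *fragment* a stress run — a day that was
the second of a run (COOLING_AND_MILK) can become the first of a new
run (COOLING) — so the count of first-day COOLING decisions alone is
not monotone in the threshold. The monotone quantity is the total
number of cooling-gate activations (COOLING plus COOLING_AND_MILK),
and that is what the monotonicity tests assert. Cooling does not
modify the next day's inputs: its physiological benefit is
unmodelled.

## Problem sizes and run times

The recovery benchmark runs the full pipeline at 200 cows × 730 days
(146,000 cow-days; 102,200 training rows; 408,800 training
observations) with 40 LM epochs — the objective and pooled R plateau
well before epoch 40 at this size, so longer budgets change nothing
but run time. The package-default epoch cap is 1000 for small
problems. Smaller fixtures (a handful of cows over one to three
months) exercise every code path in seconds.

The recovery criterion compares the pooled test R against the *noise
ceiling*: the correlation between normalized latent and observed
targets on the test rows, i.e. the score of a model that recovered
the generative response exactly. A small gap is expected even for a
perfect learner because the latent response contains cow-specific
components (the breeding-value susceptibility and the cow effect)
that are not inputs to the network.

## Known limitations

* The wet-bulb balance assumes an unventilated psychrometer
  coefficient independent of temperature; ventilated-instrument data
  would need a different A.
* The generator's heat response is instantaneous and linear above
  threshold; real lag and accumulation effects will make real-data
  recovery harder than the synthetic benchmark.
* The drafting simulation treats the model's predictions as the only
  production information; a deployed system would blend them with
  the robot's same-day measurements.
* Normalisation rejects constant columns rather than mapping them; a
  farm with, say, fixed milking frequency must drop that column
  before fitting.
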