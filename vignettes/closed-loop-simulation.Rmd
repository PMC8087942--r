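---
title: "Methods: closed-loop insulin delivery in virtual diabetic pigs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closed-loop insulin delivery in virtual diabetic pigs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigaid)
```

This vignette is the package's account of its science: the glucose–insulin
model and its assumptions, the two dosing controllers, the parameters that
matter and why they default to what they do, and what the simulator can and
cannot say about real animals.

## The problem

Automated insulin delivery (AID) systems modulate pump insulin from CGM
readings. In normal use both major open-source systems rely on the user
announcing meal carbohydrates; a *full closed loop* removes announcements,
so the controller must detect and dose unannounced meal absorption from the
glucose signal alone. Diabetic pigs are a demanding test bed for this: their
insulin kinetics are roughly twice as fast as in humans and their insulin
needs are low (basal 0.10–0.30 U/h), so mis-modelled insulin action shows up
quickly as hypo- or hyperglycemia. `pigaid` rebuilds that comparison at desk
scale: one calibrated virtual pig population, two controllers, one meal
protocol, common metrics.

## Insulin action model

Both controllers describe a subcutaneous dose by a normalized activity
curve. We use the standard two-parameter exponential model (the form both
open-source systems implement), parameterised by time-to-peak activity
`tpa` and duration of insulin action `dia`, optionally shifted by an onset
delay. The parameterisation is well defined only when the peak occurs in
the first half of the (delay-adjusted) duration; `insulin_action_curve()`
rejects anything else. By construction activity is zero outside
`(delay, dia)`, unimodal with its maximum exactly at `tpa`, integrates to
one, and insulin-on-board `iob(t) = 1 − ∫₀ᵗ activity` is available in
closed form — the test suite checks the closed form against trapezoid
quadrature at `1e-4`.

The pig model uses `tpa = 25` min and `dia = 180` min. The duration is
deliberately longer than the observed ~2 h exposure: a too-short DIA makes
a controller forget active insulin and stack doses, which pilot titration
showed as hypoglycemia. The Loop-variant curve adds a 15-min onset delay,
modelling no glucose-lowering effect at all in the first quarter hour;
*only the Loop-style controller uses this variant*. The virtual pig's true
absorption always follows the delay-free pig curve, so the Loop controller
operates under a small, intentional model mismatch — exactly the situation
of a controller configured with a curve that differs from physiology.

`fit_action_curve()` fits `A·activity(t; tpa, dia)` to concentration–time
samples by Levenberg–Marquardt least squares (`minpack.lm::nls.lm`), with
the onset delay held fixed and the curve reparameterised through
`r = (tpa−delay)/(dia−delay)` box-bounded to `(0.02, 0.48)` so every
iterate stays inside the valid parameter region.

## The virtual pig

The simulator is a single-compartment minute-step glucose balance:

```
G(t+1) = G(t) − ISF·(SC + IV insulin acting in minute t)
              + CSF·(carbohydrate absorbed in minute t)
              + ISF·basal_rate/60
```

The last term is net endogenous glucose production, chosen so that
*delivering exactly the titrated basal holds fasting glucose constant* —
which is precisely what the in-vivo basal titration established, and the
property the dosing controllers assume. Consequences tested as invariants:
with delivery suspended, glucose rises at `ISF·basal/60` per minute; a
bolus lowers glucose by exactly `ISF·units` in total; a meal raises it by
exactly `CSF·grams`, with `CSF = ISF/ICR` (the standard carb-sensitivity
identity; the calibration provides ISF and ICR but no direct carb
sensitivity).

Choices a scientist must make somewhere, made once here:

* **Meal absorption** (not measured in the calibration data): triangular
  absorption-rate profiles; *fast* (sugared applesauce-style) peaks at
  30 min, complete by 120 min; *mixed* (pig chow) peaks at 90 min, complete
  by 240 min. Total absorbed mass equals the meal's grams exactly.
* **IV insulin**: triangular activity over 90 min, peaking at 15 min —
  matching the observation that glucose stabilises about 90 min after an
  IV bolus. Used only by the ISF-determination protocol.
* **CGM**: readings every 5 min, `clamp(G + bias + N(0, σ), 40, 400)` with
  defaults `σ = 5` mg/dl and `bias = −3` mg/dl, reflecting the device
  class's slight tendency to under-read in pigs. All randomness flows
  through R's seeded RNG, so a (configuration, seed) pair reproduces a
  trace bit for bit.
* **Floor**: true glucose is clamped at 20 mg/dl to keep pathological runs
  physical. The IV ISF test therefore starts from a 300 mg/dl fasted
  state — an untreated insulin-deficient animal is hyperglycemic — so the
  full drop of a 1 U bolus is observable.
* **Basal titration** is evaluated over a full 10-h night: the accepted-rate
  band implied by the 30 mg/dl overnight-stability criterion then lies
  within one fine titration step of the true basal for every pig in the
  default herd.

The six default pigs (`study_pigs()`) carry the individually determined
dosing parameters of the calibrated herd: basal 0.10–0.30 U/h, ISF 110–167
mg/dl/U, ICR 49–90 g/U. The in-silico protocols `iv_isf_test()` and
`titrate_basal()` recover these exactly (ISF) or within one titration step
(basal); this parameter-recovery loop is what "calibrated" means here.

## The oref1-style controller

Every 5 min the controller recomputes, from the CGM history and its own
net-of-basal dose log:

1. **Deviations** — observed 5-min glucose change minus the change expected
   from insulin activity alone. Positive deviations signal unannounced
   carbohydrate.
2. **Three forecasts** over a 4-h horizon: insulin-only (`IOBpredBGs`),
   zero-temp (`ZTpredBGs`, the worst likely case with basal withheld
   counted as negative IOB), and unannounced-meal (`UAMpredBGs`), which
   extrapolates deviations by a three-case rule: continue a reasonable
   decline at its own rate; force a too-slow decline linearly to zero over
   3 h; treat a rise as peaking immediately and decaying at one-third of
   its rise rate from the recent (60-min) minimum. A decay-rate floor of
   `deviation/180 min` applies in every case so extrapolated deviations
   always reach zero within 3 h.
3. **Blending**: `minPredBG = max(min IOBpred from 90 min on,
   mean(min UAMpred from 60 min on, min ZTpred))`, then
   `insulinReq = (minPredBG − target)/ISF`.
4. **Dosing**: half the requirement as a supermicrobolus, capped by 30 min
   of scheduled basal and by the remaining max-IOB headroom, rounded down
   to the 0.05 U pump increment; the remainder as a 30-min temporary basal,
   also IOB-capped so no command sequence can push net IOB past `max_iob`.
   A nonpositive requirement yields a low or zero temporary basal.

Defaults: target 110 mg/dl (mid-range of the 70–180 euglycemic band; the
comparison is insensitive to a few mg/dl either way), `max_iob` 2 U
(several hours of the largest herd basal — generous for 0.1–0.3 U/h
animals, and the cap that in practice limits meal-time aggressiveness),
`max_temp_basal` 35 U/h (the pump ceiling).

## The Loop-style controller

A single forecast is the sum of three active components (the carbohydrate
component is identically zero without announcements):

* **Insulin effect**: expected change from the net dose log under the
  15-min-onset curve.
* **Momentum**: the 5-min rates of change over the last 20 min, weighted
  1:2:3:4 toward the most recent, extrapolated forward and blended linearly
  to zero over 30 min.
* **Retrospective correction**: each cycle stores the forecast and records
  the discrepancy between the new reading and what the previous forecast
  predicted for now. The standard correction projects the 30-min mean
  discrepancy forward as a velocity decaying over 60 min; the integral
  variant (enabled by default) adds `0.1 ×` an exponentially forgotten
  running sum of discrepancies (forgetting 0.9 per cycle), clamped to three
  times the magnitude of the standard term. The clamp ties the integral
  term to the standard term, so after a window of clean tracking the whole
  correction returns to zero; under a sustained disturbance the integral
  variant responds strictly faster — both properties are tested.

Dosing is **temp-basal only**: if any predicted point falls below the
suspend threshold (70 mg/dl), delivery stops for 30 min; otherwise the
correction units are the smaller of the eventual-glucose correction to the
target midpoint (range 100–115 mg/dl) and the headroom of the minimum
prediction above the suspend threshold, delivered as
`basal + 2·units` U/h over 30 min. The command object has no bolus field at
all.

## The challenge protocol

A simulated pig-day spans 30 h: reset at 01:00 to 120 mg/dl at steady
basal, unannounced meals at 07:30 (66 g fast), 13:30 and 19:00 (132 g mixed
each), and scoring over breakfast (6 h), lunch and dinner (5 h each) and
the *following* 01:00–07:00 overnight window — so post-dinner carryover,
the mechanism that differentiates controllers at night, can reach the
overnight score. Corrective carbohydrates (10 g fast sugar) are given when
the CGM and a confirmatory true-glucose measure both read below 55 mg/dl or
the CGM alone reads below 40, with a 30-min refractory period; any rescue
flags its window as a severe hypoglycemic event. Windows whose CGM trace
gaps for more than an hour are excluded. Aggregation is pig-first: each
pig's windows are averaged over its days before the cross-pig mean and
standard error, so unbalanced day counts cannot weight one animal over
another.

Default problem size is 6 pigs × 3 days per controller (seeds enumerated
per pig-day from a base seed); a full two-controller comparison at this
size runs in well under a minute per arm on a laptop core.

## What the simulator does and does not emulate

The generator reproduces the statistical structure the analysis needs:
steady-state fasting glucose under a titrated basal, dose-proportional
insulin and carbohydrate effects, meal-shaped deviations, 5-min sampling
with noise and bias, and seed-exact reproducibility. It deliberately omits
multi-compartment metabolism, intra-day insulin-sensitivity variation,
exercise and stress effects, dawn phenomenon, sensor dropout and
compression artifacts, and inter-day parameter drift. Passing tests
therefore demonstrate that the *controllers implement their dosing logic
correctly* and that the comparison machinery is sound — not that a live
pig would achieve the same numbers.

One consequence is visible in the bundled end-to-end runs: with matched
dynamics, clean 4-h meal absorption and an accurate insulin model, *both*
controllers return glucose to target within ~2 h of the last absorption and
hold the overnight window at or near ceiling, so the overnight contrast
between them collapses to a tie at 100% time-in-range. The ordering the
in-vivo comparison reported survives where the desk model allows
separation — overall, lunch and dinner time-in-range all favour the
oref1-style controller, and the Loop-style controller's slower unannounced
meal response shows as prolonged post-dinner hyperglycemia inside the
dinner window. Reproducing the full overnight gap would require slower,
more variable chow absorption and overnight physiology this generator does
not claim to model.

## Numerical choices

* Continuous curve formulas; the simulator evaluates them on a 1-min grid,
  using exact per-minute absorbed fractions `iob(m−1) − iob(m)` so dose
  mass is conserved to machine precision.
* Forecast arrays run at 5-min steps over a 240-min horizon, clamped below
  at 39 mg/dl (the CGM's "LOW" region) for the oref1-style scenarios.
* SMBs round *down* to the 0.05 U pump increment; ties in the cap
  comparison resolve toward less insulin.
* Temp basals are re-evaluated every cycle but enacted with a 30-min
  duration, so a missed cycle fails safe toward the scheduled rate after
  half an hour.
* Deviation intervals spanning a CGM gap over 10 min are skipped as `NA`
  and never fed to the UAM extrapolation.
* Degenerate inputs error early: empty metric windows are undefined rather
  than zero; all-zero PK samples refuse to fit; titration that cannot
  stabilise within its iteration cap raises rather than returning the last
  candidate.

## Known limitations

Beyond the physiological simplifications above: the oref1-style
implementation covers the no-announcement code path only (no carbohydrate
bookkeeping, no autosens/autotune adaptation, and only the documented
blending rule, not every guard clause of the reference implementation); the
Loop-style integral-correction gains are qualitative contracts rather than
a line-by-line port; and the rescue rule's confirmatory measurement is the
simulator's true glucose, standing in for an ear-prick reading.
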