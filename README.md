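# pigaid

Desk-scale simulation of **full closed-loop insulin delivery** — automated
dosing with *no meal announcements* — in virtual insulin-deficient pigs.
The package is aimed at researchers comparing artificial-pancreas dosing
algorithms: it reimplements the two dominant open-source control strategies
against a common, calibrated glucose–insulin simulator and scores them with
the standard time-in-range metrics, so algorithm features (microboluses,
unannounced-meal forecasting, retrospective correction) can be studied in
isolation from hardware and animal variability.

## What is inside

**Insulin model.** Both controllers share the exponential insulin-activity
model used by open-source AID systems, parameterised by time-to-peak
activity (TPA) and duration of insulin action (DIA). With
`td = dia − delay`, `tp = tpa − delay`, `s = t − delay`:

    τ = tp·(1 − tp/td) / (1 − 2·tp/td)
    a = 2τ/td
    S = 1 / (1 − a + (1 + a)·e^(−td/τ))

    activity(s) = (S/τ²) · s · (1 − s/td) · e^(−s/τ)
    IOB(s)      = 1 − S·(1 − a)·[(s²/(τ·td·(1 − a)) − s/τ − 1)·e^(−s/τ) + 1]

Activity integrates to exactly one over the duration of action and peaks at
TPA. The fitted pig model (porcine lispro kinetics are faster than human)
uses TPA 25 min and DIA 3 h; the Loop variant adds a 15-min onset delay.
`fit_action_curve()` recovers TPA/DIA from pharmacokinetic samples by
Levenberg–Marquardt least squares.

**Virtual pig.** A minute-step glucose balance
`ΔG = −ISF·(insulin acting) + CSF·(carbs absorbing) + ISF·basal/60`,
built so that delivering exactly the titrated basal holds glucose constant.
Six calibrated virtual pigs (basal 0.10–0.30 U/h, ISF 110–167 mg/dl/U) ship
as `study_pigs()`; the in-vivo parameter-determination protocols exist as
in-silico experiments (`iv_isf_test()`, `titrate_basal()`) that recover the
configured parameters. A CGM samples the state every 5 min with seedable
noise and a slight negative bias.

**Controllers.** `oref1_decide()` implements the oref1-style logic:
deviation calculus, three parallel forecasts (insulin-only, zero-temp,
unannounced-meal), blending to `minPredBG`, `insulinReq = (minPredBG −
target)/ISF`, and supermicrobolus dosing capped by half the requirement,
30 min of basal, and the max-IOB headroom. `loop_decide()` implements the
Loop-style logic: a single forecast summing insulin effect, glucose
momentum and (integral) retrospective correction, a suspend threshold, and
temp-basal-only dosing.

**Protocol.** `run_challenge()` feeds each pig an unannounced 66 g fast
breakfast and two 132 g mixed meals per day, monitors four windows
(breakfast 6 h, lunch/dinner 5 h, overnight 01:00–07:00), applies the
two-measure/<40 rescue rule (10 g fast sugar), and aggregates
time-in-range, time-below-70 and insulin delivered across pigs.

## Worked example

```r
library(pigaid)
pig <- study_pigs()[[4]]
pig
#> Virtual pig 4: basal 0.30 U/h, ISF 158 mg/dl/U, ICR 59 g/U

tr <- simulate_closed_loop(pig, "oref1", seed = 1)
tr
#> Closed-loop trace: pig 4, oref1 controller, 1800 min, 360 CGM readings
#>   true glucose 93-210 mg/dl; 416 events (0 rescues)

window_metrics(tr)[, c("meal", "tir", "below70", "above180", "insulin_u")]
#>       meal   tir below70 above180 insulin_u
#>  breakfast  95.8       0     4.17      2.93
#>      lunch  81.7       0    18.33      3.82
#>     dinner  78.3       0    21.67      3.79
#>  overnight 100.0       0     0.00      1.82
```

One simulated pig-day spans 30 h: it starts at 01:00 at steady state,
runs through the three unannounced meals, and ends with the following
overnight window. Here the controller holds the pig in range 96% of the
breakfast window and the whole night, at the cost of transient post-meal
hyperglycemia after the two large mixed meals (no hypoglycemia, no
rescues); `insulin_u` is the total insulin delivered in each window.
`run_challenge()` repeats this over pigs and days and reports mean ± SE per
window and controller.

A command-line surface wraps the same functions:

```sh
Rscript -e 'quit(status = pigaid::pigaid_cli())' -- run-challenge --controller oref1 --days 1 --seed 7 --out out/
```

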