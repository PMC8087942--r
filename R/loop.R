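# Loop-style dosing logic: a single model-predictive forecast built from the
# insulin effect, glucose momentum and (integral) retrospective correction,
# a suspend threshold, and temp-basal-only dosing.

#' Configuration of the Loop-style controller
#'
#' @param target_range correction target range `(low, high)`, mg/dl.
#' @param suspend_threshold glucose below which all delivery stops, mg/dl;
#'   must lie below the target range.
#' @param momentum_window span of glucose history feeding momentum, minutes.
#' @param momentum_blend minutes over which the momentum effect blends
#'   linearly to zero.
#' @param rc_window span of forecast discrepancies averaged by retrospective
#'   correction, minutes.
#' @param rc_decay_horizon minutes over which the correction velocity decays
#'   linearly to zero.
#' @param integral_rc use integral retrospective correction (adds an
#'   exponentially forgotten running sum of discrepancies for more rapid
#'   adaptation).
#' @param integral_gain gain on the running discrepancy sum.
#' @param integral_cap_mult the integral term is clamped to this multiple of
#'   the magnitude of the standard (mean-discrepancy) term.
#' @param rc_forgetting per-cycle forgetting factor of the running sum.
#' @param horizon forecast horizon, minutes.
#' @param step forecast/cycle step, minutes.
#' @param max_temp_basal pump ceiling for temporary basal rates, U/h.
#' @param n_stored_forecasts number of past forecasts retained for
#'   discrepancy computation.
#' @return An object of class `loop_config`.
#' @export
loop_config <- function(target_range = c(100, 115), suspend_threshold = 70,
                        momentum_window = 20, momentum_blend = 30,
                        rc_window = 30, rc_decay_horizon = 60,
                        integral_rc = TRUE, integral_gain = 0.1,
                        integral_cap_mult = 3, rc_forgetting = 0.9,
                        horizon = 240, step = 5, max_temp_basal = 35,
                        n_stored_forecasts = 12) {
  stopifnot(length(target_range) == 2, target_range[1] < target_range[2])
  if (!(suspend_threshold < target_range[1])) {
    stop("suspend_threshold must lie below the target range")
  }
  if (!(horizon > 0 && momentum_blend > 0 && rc_decay_horizon > 0)) {
    stop("horizons must be positive")
  }
  structure(list(target_range = target_range,
                 suspend_threshold = suspend_threshold,
                 momentum_window = momentum_window,
                 momentum_blend = momentum_blend, rc_window = rc_window,
                 rc_decay_horizon = rc_decay_horizon, integral_rc = integral_rc,
                 integral_gain = integral_gain,
                 integral_cap_mult = integral_cap_mult,
                 rc_forgetting = rc_forgetting, horizon = horizon, step = step,
                 max_temp_basal = max_temp_basal,
                 n_stored_forecasts = n_stored_forecasts),
            class = "loop_config")
}

#' Insulin effect component of the Loop forecast
#'
#' Cumulative expected glucose change from delivered insulin relative to the
#' scheduled basal, using the Loop-variant action curve (no effect in the
#' first 15 min after a dose).
#'
#' @param dose_log net-of-basal dose log (`time`, `units`).
#' @param curve the Loop-variant [insulin_action_curve()].
#' @param isf mg/dl per U.
#' @param config a [loop_config()].
#' @param now current time on the dose-log clock, minutes.
#' @return Delta-BG vector at offsets `0, step, ..., horizon` (starts at 0).
#' @export
loop_insulin_effect <- function(dose_log, curve, isf, config, now = 0) {
  offsets <- seq(0, config$horizon, by = config$step)
  dose_t <- if (is.null(dose_log)) numeric(0) else dose_log$time
  dose_u <- if (is.null(dose_log)) numeric(0) else dose_log$units
  -pred_decline(dose_t, dose_u, curve, isf, now, offsets)
}

#' Glucose momentum component
#'
#' The 5-min rates of change over the prior `momentum_window` are combined
#' with linearly increasing weight on more recent rates (1:2:3:4 for the
#' default 20-min window) and the weighted rate is extrapolated forward,
#' blending linearly to zero over `momentum_blend` minutes. Fewer than four
#' available deltas yield zero momentum.
#'
#' @param history list/data frame with `time`, `reading` at 5-min spacing.
#' @param config a [loop_config()].
#' @return Delta-BG vector at offsets `0, step, ..., horizon`.
#' @export
loop_momentum <- function(history, config) {
  offsets <- seq(0, config$horizon, by = config$step)
  K <- length(offsets) - 1
  n_delta <- config$momentum_window / config$step
  tt <- history$time; rr <- history$reading
  n <- length(tt)
  if (n < n_delta + 1 ||
      any(diff(tt[(n - n_delta):n]) != config$step)) {
    return(numeric(K + 1))
  }
  deltas <- diff(rr[(n - n_delta):n])
  w <- seq_len(n_delta)
  rate <- sum(w * deltas) / sum(w)               # mg/dl per step
  blend <- pmax(0, 1 - (seq_len(K) - 1) * config$step / config$momentum_blend)
  c(0, cumsum(rate * blend))
}

#' Retrospective correction component
#'
#' Each cycle, the discrepancy between the observed glucose and the value
#' the previous forecast predicted for now is recorded. The standard
#' correction projects the mean discrepancy over `rc_window` forward as a
#' velocity that decays linearly to zero over `rc_decay_horizon`; the
#' integral variant adds `integral_gain` times an exponentially forgotten
#' running sum of the discrepancies, clamped to `integral_cap_mult` times the
#' magnitude of the standard term, for more rapid adaptation to sustained
#' forecast error. No stored discrepancies yield a zero correction.
#'
#' @param discrepancies numeric vector of recent per-cycle discrepancies
#'   (observed minus previously predicted, mg/dl), oldest first.
#' @param config a [loop_config()].
#' @return Delta-BG vector at offsets `0, step, ..., horizon`.
#' @export
loop_retrospective <- function(discrepancies, config) {
  offsets <- seq(0, config$horizon, by = config$step)
  K <- length(offsets) - 1
  d <- discrepancies[!is.na(discrepancies)]
  if (length(d) == 0) return(numeric(K + 1))
  m <- mean(utils::tail(d, config$rc_window / config$step))
  corr <- m
  if (config$integral_rc) {
    lam <- config$rc_forgetting
    s <- sum(d * lam^(rev(seq_along(d)) - 1))
    cap <- config$integral_cap_mult * abs(m)
    corr <- m + max(-cap, min(cap, config$integral_gain * s))
  }
  decay <- pmax(0, 1 - (seq_len(K) - 1) * config$step / config$rc_decay_horizon)
  c(0, cumsum(corr * decay))
}

#' Assemble the Loop forecast
#'
#' `predicted(t) = current_bg + insulin(t) + momentum(t) + retrospective(t)`;
#' the carbohydrate component is identically zero without meal
#' announcements. Reports the eventual (terminal) and minimum predicted
#' glucose used for dosing.
#'
#' @param current_bg current glucose, mg/dl.
#' @param insulin,momentum,retrospective component delta-BG vectors on a
#'   shared time base.
#' @param config a [loop_config()].
#' @return An object of class `loop_forecast` with elements `predicted`,
#'   `components`, `eventual`, `min_pred`.
#' @export
loop_forecast <- function(current_bg, insulin, momentum, retrospective, config) {
  stopifnot(length(insulin) == length(momentum),
            length(insulin) == length(retrospective))
  predicted <- current_bg + insulin + momentum + retrospective
  structure(list(
    predicted = predicted,
    components = list(insulin = insulin, momentum = momentum,
                      retrospective = retrospective),
    eventual = predicted[length(predicted)],
    min_pred = min(predicted)
  ), class = "loop_forecast")
}

#' Loop-style temp-basal recommendation
#'
#' Temp basal only, never a bolus. If any predicted glucose falls below the
#' suspend threshold, delivery stops (0 U/h for 30 min). Otherwise the
#' correction units are the smaller of the eventual-glucose correction to the
#' target midpoint and the headroom of the minimum prediction above the
#' suspend threshold, delivered by adjusting the scheduled basal over 30 min
#' (rate = basal + 2 x units per hour, clamped to `[0, max_temp_basal]`).
#'
#' @param forecast a [loop_forecast()].
#' @param settings list with `basal` (U/h) and `isf` (mg/dl per U).
#' @param config a [loop_config()].
#' @return A `dose_command` with `temp_basal`, `duration` and `reason`
#'   (no bolus field).
#' @export
loop_recommend <- function(forecast, settings, config) {
  stopifnot(inherits(forecast, "loop_forecast"))
  if (forecast$min_pred < config$suspend_threshold) {
    return(structure(list(temp_basal = 0, duration = 30,
                          reason = sprintf("suspend: min predicted %.0f < %.0f",
                                           forecast$min_pred,
                                           config$suspend_threshold)),
                     class = "dose_command"))
  }
  mid <- mean(config$target_range)
  units <- min((forecast$eventual - mid) / settings$isf,
               (forecast$min_pred - config$suspend_threshold) / settings$isf)
  rate <- min(max(settings$basal + 2 * units, 0), config$max_temp_basal)
  structure(list(temp_basal = rate, duration = 30,
                 reason = sprintf("eventual %.0f, min %.0f, units %.2f",
                                  forecast$eventual, forecast$min_pred, units)),
            class = "dose_command")
}

#' One Loop-style dosing decision
#'
#' Builds the three active forecast components from the CGM history, the
#' net dose log and the recent forecast discrepancies, assembles the
#' forecast, and issues the temp-basal command. The assembled forecast is
#' attached as the `"forecast"` attribute so the caller can store it for the
#' next cycle's discrepancy.
#'
#' @inheritParams oref1_decide
#' @param discrepancies recent per-cycle forecast discrepancies, oldest
#'   first.
#' @return A `dose_command` (temp basal only).
#' @export
loop_decide <- function(history, dose_t, dose_u, discrepancies, curve,
                        settings, config, now) {
  dose_log <- list(time = dose_t, units = dose_u)
  current_bg <- history$reading[length(history$reading)]
  ins <- loop_insulin_effect(dose_log, curve, settings$isf, config, now)
  mom <- loop_momentum(history, config)
  rc <- loop_retrospective(discrepancies, config)
  fc <- loop_forecast(current_bg, ins, mom, rc, config)
  cmd <- loop_recommend(fc, settings, config)
  attr(cmd, "forecast") <- fc
  cmd
}
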