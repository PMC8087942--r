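# oref1-style dosing logic: deviation calculus, three parallel forecasts
# (insulin-only, zero-temp, unannounced meal), blending to a minimum
# predicted glucose, insulin requirement, and SMB / temp-basal dosing.

#' Configuration of the oref1-style controller
#'
#' @param target target glucose, mg/dl (80-200).
#' @param max_iob insulin-on-board ceiling, U: the controller never lets net
#'   IOB from its own commands exceed this.
#' @param max_temp_basal pump ceiling for temporary basal rates, U/h.
#' @param smb_enabled allow supermicroboluses.
#' @param uam_enabled include the unannounced-meal forecast.
#' @param horizon forecast horizon, minutes.
#' @param step forecast/cycle step, minutes.
#' @param smb_increment pump bolus granularity, U.
#' @return An object of class `oref1_config`.
#' @export
oref1_config <- function(target = 110, max_iob = 2, max_temp_basal = 35,
                         smb_enabled = TRUE, uam_enabled = TRUE,
                         horizon = 240, step = 5, smb_increment = 0.05) {
  if (!(target >= 80 && target <= 200)) stop("target must be in [80, 200] mg/dl")
  if (!(max_iob > 0)) stop("max_iob must be positive")
  if (!(max_temp_basal > 0)) stop("max_temp_basal must be positive")
  structure(list(target = target, max_iob = max_iob,
                 max_temp_basal = max_temp_basal, smb_enabled = smb_enabled,
                 uam_enabled = uam_enabled, horizon = horizon, step = step,
                 smb_increment = smb_increment),
            class = "oref1_config")
}

# expected BG change from the net dose log over [t1, t2]:
# -isf * sum_d u_d * (iob(t1 - td) - iob(t2 - td))
expected_bg_delta <- function(dose_t, dose_u, curve, isf, t1, t2) {
  if (length(dose_t) == 0) return(0)
  -isf * sum(dose_u * (insulin_iob(curve, t1 - dose_t) -
                         insulin_iob(curve, t2 - dose_t)))
}

#' Glucose deviations from insulin-expected change
#'
#' For each 5-min interval, the deviation is the observed glucose change
#' minus the change expected from insulin activity alone (scheduled basal is
#' neutral; the dose log holds net-of-schedule insulin). Positive deviations
#' indicate unannounced carbohydrate absorption or other unmodelled rise.
#' Intervals spanning a sensor gap longer than 10 min are returned as `NA`.
#'
#' @param history data frame (or list) with `time` (minutes) and `reading`
#'   (mg/dl) at 5-min spacing; at least 4 readings.
#' @param curve the controller's [insulin_action_curve()].
#' @param isf insulin sensitivity factor, mg/dl per U.
#' @param dose_log data frame (or list) with `time` and `units` of
#'   net-of-basal doses; may be empty.
#' @return data frame with `time` (interval end) and `deviation`
#'   (mg/dl per interval).
#' @export
compute_deviations <- function(history, curve, isf, dose_log = NULL) {
  tt <- history$time; rr <- history$reading
  if (length(tt) < 4) stop("need at least 4 readings for deviation work")
  dose_t <- if (is.null(dose_log)) numeric(0) else dose_log$time
  dose_u <- if (is.null(dose_log)) numeric(0) else dose_log$units
  n <- length(tt)
  dev <- numeric(n - 1)
  for (i in 2:n) {
    if (tt[i] - tt[i - 1] > 10) {
      dev[i - 1] <- NA_real_
      next
    }
    exp_d <- expected_bg_delta(dose_t, dose_u, curve, isf, tt[i - 1], tt[i])
    dev[i - 1] <- (rr[i] - rr[i - 1]) - exp_d
  }
  data.frame(time = tt[-1], deviation = dev)
}

# decline(k) = isf * sum_d u_d * (iob(now - td) - iob(now - td + off_k))
pred_decline <- function(dose_t, dose_u, curve, isf, now, offsets) {
  if (length(dose_t) == 0) return(numeric(length(offsets)))
  ages <- now - dose_t
  iob_now <- insulin_iob(curve, ages)
  fut <- outer(ages, offsets, `+`)
  iob_fut <- matrix(insulin_iob(curve, fut), nrow = length(ages))
  isf * colSums(dose_u * (iob_now - iob_fut))
}

#' Insulin-only glucose forecast (IOBpredBGs)
#'
#' Glucose path under the remaining action of already-delivered insulin,
#' with no carbohydrate absorption: flat once all insulin on board decays.
#' Values are clamped at 39 mg/dl.
#'
#' @param current_bg current glucose, mg/dl.
#' @param dose_log net-of-basal dose log (`time`, `units`).
#' @param curve the controller's [insulin_action_curve()].
#' @param isf mg/dl per U.
#' @param config an [oref1_config()].
#' @param now current time on the dose-log clock, minutes.
#' @return Numeric vector at times `now + 0, step, ..., horizon`.
#' @export
predict_iob <- function(current_bg, dose_log, curve, isf, config, now = 0) {
  offsets <- seq(0, config$horizon, by = config$step)
  dose_t <- if (is.null(dose_log)) numeric(0) else dose_log$time
  dose_u <- if (is.null(dose_log)) numeric(0) else dose_log$units
  pmax(39, current_bg - pred_decline(dose_t, dose_u, curve, isf, now, offsets))
}

#' Zero-temp glucose forecast (ZTpredBGs)
#'
#' The worst-likely-case path: carbohydrate absorption ceases now and basal
#' delivery is suspended, the withheld basal counting as negative insulin on
#' board. Pointwise at or above the insulin-only forecast whenever the basal
#' rate is positive.
#'
#' @inheritParams predict_iob
#' @param basal scheduled basal rate, U/h.
#' @return Numeric vector at times `now + 0, step, ..., horizon`.
#' @export
predict_zt <- function(current_bg, dose_log, curve, isf, basal, config, now = 0) {
  offsets <- seq(0, config$horizon, by = config$step)
  iobp <- predict_iob(current_bg, dose_log, curve, isf, config, now)
  # a basal minute withheld at now+j has acted (1 - iob(t-j)) by offset t:
  # total withheld action at offset t is (b/60) * sum_{a=1..t} (1 - iob(a))
  acted <- cumsum(1 - insulin_iob(curve, seq_len(config$horizon)))
  withheld <- (basal / 60) * c(0, acted[offsets[-1]])
  pmax(39, iobp + isf * withheld)
}

#' Unannounced-meal glucose forecast (UAMpredBGs)
#'
#' Extrapolates recent deviations forward and integrates them on top of the
#' insulin-only path. Once deviations have peaked and are decreasing at a
#' reasonable rate, they are assumed to keep decreasing at that rate until
#' they reach zero; if they are decreasing too slowly, they are forced to
#' decline linearly to zero over 3 h; if they are still increasing, they are
#' assumed to peak immediately and decay at one-third of the rate at which
#' they rose from their recent minimum (last 60 min). Extrapolated deviations
#' reach zero within 3 h in every case and stay there.
#'
#' @param current_bg current glucose, mg/dl.
#' @param deviations numeric vector of recent deviations (mg/dl per 5-min
#'   interval), oldest first; at least 3.
#' @param iob_pred the matching [predict_iob()] output.
#' @param config an [oref1_config()].
#' @return Numeric vector on the same time base as `iob_pred`.
#' @export
predict_uam <- function(current_bg, deviations, iob_pred, config) {
  d <- deviations[!is.na(deviations)]
  if (length(d) < 3) stop("need at least 3 recent deviations for the UAM forecast")
  K <- length(iob_pred) - 1
  d0 <- d[length(d)]
  if (d0 <= 0 || all(d == 0)) return(iob_pred)
  slope <- d[length(d)] - d[length(d) - 1]
  floor_rate <- d0 / (180 / config$step)   # linear-to-zero over 3 h
  if (slope < 0) {
    rate <- max(-slope, floor_rate)
  } else {
    recent <- utils::tail(d, 60 / config$step)
    imin <- which.min(recent)
    rise_steps <- length(recent) - imin
    r_up <- if (rise_steps > 0) (d0 - recent[imin]) / rise_steps else 0
    rate <- max(r_up / 3, floor_rate)
  }
  fut <- pmax(0, d0 - rate * seq_len(K))
  pmax(39, iob_pred + c(0, cumsum(fut)))
}

#' Blend the forecast minima into minPredBG
#'
#' minPredBG is the maximum of (a) the lowest insulin-only prediction from
#' 90 min onwards and (b) the average of the lowest unannounced-meal
#' prediction from 60 min onwards and the lowest zero-temp prediction over
#' the whole horizon. Without a UAM forecast the zero-temp minimum stands in
#' for the average.
#'
#' @param predictions list with elements `iob`, `zt` and optionally `uam`,
#'   each a vector at times `0, step, ..., horizon`.
#' @param config an [oref1_config()].
#' @return minPredBG, mg/dl.
#' @export
min_pred_bg <- function(predictions, config) {
  times <- seq(0, config$horizon, by = config$step)
  min_iob <- min(predictions$iob[times >= 90])
  min_zt <- min(predictions$zt)
  if (!is.null(predictions$uam)) {
    min_uam <- min(predictions$uam[times >= 60])
    max(min_iob, (min_uam + min_zt) / 2)
  } else {
    max(min_iob, min_zt)
  }
}

#' Insulin requirement
#'
#' `(minPredBG - target) / ISF`; negative when the minimum predicted glucose
#' is below target.
#'
#' @param min_pred_bg minPredBG, mg/dl.
#' @param target target glucose, mg/dl.
#' @param isf mg/dl per U.
#' @return Units of insulin (may be negative).
#' @export
insulin_req <- function(min_pred_bg, target, isf) {
  stopifnot(isf > 0)
  (min_pred_bg - target) / isf
}

#' One oref1-style dosing decision
#'
#' Composes the deviation calculus, the three forecasts, the minPredBG blend
#' and the dosing rule into a single command. When insulin is required and
#' SMBs are enabled, the microbolus is the smallest of half the requirement,
#' 30 min of the scheduled basal rate, and the remaining `max_iob` headroom,
#' rounded down to the pump increment; the remainder is expressed as a 30-min
#' temporary basal (also IOB-capped). A nonpositive requirement yields a
#' low/zero temporary basal.
#'
#' @param history list/data frame with `time`, `reading` (5-min CGM history).
#' @param dose_t,dose_u net-of-basal dose log times (min) and units (U).
#' @param curve the controller's [insulin_action_curve()].
#' @param settings list with `basal` (U/h) and `isf` (mg/dl per U).
#' @param config an [oref1_config()].
#' @param now current time, minutes.
#' @return A `dose_command`: `smb` (U), `temp_basal` (U/h), `duration`
#'   (min), `reason`.
#' @export
oref1_decide <- function(history, dose_t, dose_u, curve, settings, config, now) {
  dose_log <- list(time = dose_t, units = dose_u)
  current_bg <- history$reading[length(history$reading)]

  preds <- list(
    iob = predict_iob(current_bg, dose_log, curve, settings$isf, config, now),
    zt = predict_zt(current_bg, dose_log, curve, settings$isf, settings$basal,
                    config, now)
  )
  if (config$uam_enabled && length(history$time) >= 4) {
    # only the recent deviations feed the UAM forecast
    keep <- max(1, length(history$time) - 16):length(history$time)
    recent <- list(time = history$time[keep], reading = history$reading[keep])
    devs <- compute_deviations(recent, curve, settings$isf, dose_log)$deviation
    devs <- utils::tail(devs[!is.na(devs)], 12)
    if (length(devs) >= 3) {
      preds$uam <- predict_uam(current_bg, devs, preds$iob, config)
    }
  }
  mpb <- min_pred_bg(preds, config)
  req <- insulin_req(mpb, config$target, settings$isf)

  current_iob <- if (length(dose_t)) {
    sum(dose_u * insulin_iob(curve, now - dose_t))
  } else 0
  headroom <- max(0, config$max_iob - current_iob)

  if (req > 0) {
    smb <- 0
    caps <- c(half_req = req / 2, basal_30min = settings$basal / 2,
              iob_headroom = headroom)
    if (config$smb_enabled) {
      smb <- floor(max(0, min(caps)) / config$smb_increment + 1e-9) *
        config$smb_increment
    }
    remainder <- max(0, req - smb)
    extra_rate <- min(2 * remainder, 2 * max(0, headroom - smb))
    rate <- min(settings$basal + extra_rate, config$max_temp_basal)
    reason <- sprintf("minPredBG %.0f, insulinReq %.2f U, cap %s",
                      mpb, req, names(caps)[which.min(caps)])
  } else {
    smb <- 0
    rate <- max(0, settings$basal + 2 * req)
    reason <- sprintf("minPredBG %.0f, insulinReq %.2f U, low-temp", mpb, req)
  }
  structure(list(smb = smb, temp_basal = rate, duration = 30, reason = reason,
                 min_pred_bg = mpb, insulin_req = req),
            class = "dose_command")
}

#' @export
print.dose_command <- function(x, ...) {
  if (!is.null(x$smb)) cat(sprintf("SMB %.2f U; ", x$smb))
  cat(sprintf("temp basal %.2f U/h for %d min (%s)\n",
              x$temp_basal, x$duration, x$reason))
  invisible(x)
}
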