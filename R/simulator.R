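# Minute-step glucose engine for the virtual pig.
#
# Glucose balance per minute:
#   dG = -ISF * (SC activity + IV activity)  [insulin, U acting this minute]
#        + CSF * carbs absorbed this minute  [g]
#        + EGP_net
# with EGP_net = ISF * basal_rate / 60, so that delivering exactly the
# configured basal holds glucose constant. Activity buffers are filled by
# convolving each dose with a per-minute absorption kernel.

# Per-minute subcutaneous absorption kernel: exact fraction of a dose acting
# in minute m, iob(m-1) - iob(m); sums to 1 by construction.
sc_kernel <- function(curve) {
  m <- seq_len(ceiling(curve$dia))
  insulin_iob(curve, m - 1) - insulin_iob(curve, m)
}

# IV insulin acts fast: triangular activity over 90 min with peak at 15 min
# (glucose takes ~90 min to stabilise after an IV bolus), normalised to 1.
iv_kernel <- function(duration = 90, peak = 15) {
  m <- seq_len(duration) - 0.5
  r <- ifelse(m <= peak, m / peak, (duration - m) / (duration - peak))
  r / sum(r)
}

# Triangular meal absorption-rate profiles (g/min shape, normalised to 1):
# fast carbohydrate peaks at 30 min and completes by 120 min; mixed meals
# peak at 90 min and complete by 240 min.
meal_kernel <- function(profile = c("fast", "mixed")) {
  profile <- match.arg(profile)
  par <- switch(profile, fast = c(peak = 30, end = 120),
                mixed = c(peak = 90, end = 240))
  m <- seq_len(par[["end"]]) - 0.5
  r <- ifelse(m <= par[["peak"]], m / par[["peak"]],
              (par[["end"]] - m) / (par[["end"]] - par[["peak"]]))
  r / sum(r)
}

# Add `units * kernel` into buffer positions t+1 .. t+L (dose at time t acts
# from the following minute on). Buffers carry a margin so no clipping logic
# is needed for doses near the end of the run.
add_kernel <- function(buf, t, units, kernel) {
  idx <- (t + 1):(t + length(kernel))
  buf[idx] <- buf[idx] + units * kernel
  buf
}

# Steady-state prewarm: contributions of an infinite history of per-minute
# doses at `rate` U/h, so that the run starts with the absorption tail a
# steady basal infusion would have produced.
prewarm_sc <- function(buf, rate, kernel) {
  tail_sums <- rev(cumsum(rev(kernel)))        # sum(kernel[m..L])
  L <- length(kernel)
  m <- seq_len(L - 1)
  buf[m] <- buf[m] + (rate / 60) * (tail_sums[-1])[m]
  buf
}

GLUCOSE_FLOOR <- 20  # simulator floor, mg/dl; keeps the state physical

#' Open-loop virtual pig run
#'
#' Simulates the pig minute by minute at a fixed subcutaneous delivery rate,
#' with optional meals, subcutaneous boluses and intravenous doses, starting
#' from the steady state of `prewarm_rate`. The workhorse behind the
#' in-silico parameter-determination protocols and the conservation
#' properties of the glucose balance.
#'
#' @param pig a [pig_params()] object.
#' @param rate delivered subcutaneous rate, U/h.
#' @param minutes run length.
#' @param curve subcutaneous absorption model.
#' @param meals list of `list(time, grams, profile)` (times in minutes from
#'   the run start).
#' @param sc_boluses,iv_doses lists of `list(time, units)`.
#' @param init_glucose starting glucose, mg/dl.
#' @param prewarm_rate rate whose absorption tail the run starts with.
#' @return True glucose at minutes `0..minutes`.
#' @export
run_open_loop <- function(pig, rate, minutes, curve = pig_insulin_curve(),
                          meals = list(), sc_boluses = list(),
                          iv_doses = list(),
                          init_glucose = 120, prewarm_rate = rate) {
  kern <- sc_kernel(curve)
  margin <- length(kern) + 300
  act_sc <- numeric(minutes + margin)
  act_iv <- numeric(minutes + margin)
  carbs <- numeric(minutes + margin)
  act_sc <- prewarm_sc(act_sc, prewarm_rate, kern)
  ivk <- iv_kernel()
  for (d in iv_doses) act_iv <- add_kernel(act_iv, d$time, d$units, ivk)
  for (d in sc_boluses) act_sc <- add_kernel(act_sc, d$time, d$units, kern)
  for (m in meals) carbs <- add_kernel(carbs, m$time, m$grams, meal_kernel(m$profile))
  for (t in 0:(minutes - 1)) act_sc <- add_kernel(act_sc, t, rate / 60, kern)

  csf <- carb_sensitivity(pig)
  egp <- pig$isf * pig$basal_rate / 60
  g <- numeric(minutes + 1)
  g[1] <- init_glucose
  for (i in seq_len(minutes)) {
    g[i + 1] <- max(GLUCOSE_FLOOR,
                    g[i] - pig$isf * (act_sc[i] + act_iv[i]) + csf * carbs[i] + egp)
  }
  g
}

#' In-silico intravenous insulin sensitivity test
#'
#' Reproduces the ISF determination protocol: with the pig fasted and at
#' steady state under its basal infusion, deliver a 1 U intravenous bolus and
#' read the glucose drop once it has stabilised (~90 min). Sensing is
#' noise-free; the returned sensitivity is `(glucose before - glucose at
#' stabilisation) / dose`.
#'
#' The test is run from a hyperglycemic fasted steady state (300 mg/dl, as
#' an untreated insulin-deficient pig presents) so the full glucose drop is
#' observable.
#'
#' @param pig a [pig_params()] object.
#' @param dose IV bolus, U (default 1).
#' @param init_glucose fasted starting glucose, mg/dl.
#' @return Measured ISF, mg/dl per U (0 for a zero dose).
#' @export
iv_isf_test <- function(pig, dose = 1, init_glucose = 300) {
  stopifnot(inherits(pig, "pig_params"), dose >= 0)
  if (dose == 0) return(0)
  t_dose <- 10
  g <- run_open_loop(pig, rate = pig$basal_rate, minutes = t_dose + 110,
                     init_glucose = init_glucose,
                     iv_doses = list(list(time = t_dose, units = dose)))
  (g[t_dose + 1] - g[length(g)]) / dose
}

#' In-silico overnight basal titration
#'
#' Reproduces the basal-determination protocol: run a full overnight window
#' (10 h by default) at a candidate rate and iteratively adjust it by `step`
#' until the glucose change over the window stays within `tol` mg/dl of the
#' starting value. Each candidate night starts from the steady state of its
#' own rate, as a pig that has been on that rate would.
#'
#' @param pig a [pig_params()] object.
#' @param start_rate first candidate rate, U/h (> 0).
#' @param step titration increment, U/h.
#' @param window_min length of the overnight window, minutes.
#' @param tol allowed absolute overnight glucose change, mg/dl.
#' @param max_iter iteration cap; exceeded means non-convergence (error).
#' @return Converged basal rate, U/h.
#' @export
titrate_basal <- function(pig, start_rate, step = 0.05, window_min = 600,
                          tol = 30, max_iter = 60) {
  stopifnot(inherits(pig, "pig_params"), start_rate > 0, step > 0)
  rate <- start_rate
  for (iter in seq_len(max_iter)) {
    g <- run_open_loop(pig, rate = rate, minutes = window_min)
    dg <- g[length(g)] - g[1]
    if (abs(dg) <= tol) return(rate)
    rate <- rate + if (dg > 0) step else -step
    if (rate <= 0) stop("titration drove the basal rate to zero")
  }
  stop("basal titration did not converge within ", max_iter, " iterations")
}

#' Simulate one closed-loop pig-day
#'
#' Runs the virtual pig minute by minute under one of the two dosing
#' controllers, with a 5-min CGM cycle, the daily meal schedule, and the
#' hypoglycemia rescue rule. The run starts at 01:00 with glucose at
#' `init_glucose` and the pig at steady state under its scheduled basal, and
#' covers `hours` hours, so the default 30 h span runs through breakfast,
#' lunch and dinner and ends with the following 01:00-07:00 overnight window.
#'
#' Every 5 minutes the controller receives the new CGM reading and the
#' delivery history and issues a dose command (microbolus and/or 30-min
#' temporary basal for the oref1-style controller; temporary basal only for
#' the Loop-style controller). Corrective carbohydrates (10 g fast) are given
#' when the CGM and a confirmatory true-glucose measurement are both below
#' 55 mg/dl, or when the CGM alone reads below 40 mg/dl; a 30-min refractory
#' period separates rescues.
#'
#' @param pig a [pig_params()] object.
#' @param controller `"oref1"` or `"loop"`.
#' @param config controller configuration ([oref1_config()] or
#'   [loop_config()]); defaults per controller.
#' @param schedule a [challenge_schedule()].
#' @param sensor a [cgm_sensor()].
#' @param hours simulated span in hours.
#' @param start_clock clock time of the start, minutes after midnight
#'   (default 60 = 01:00).
#' @param init_glucose starting true glucose, mg/dl.
#' @param seed optional RNG seed for the CGM noise; identical seed and
#'   configuration give a bit-identical trace.
#' @return An object of class `sim_trace`: true glucose per minute, CGM
#'   readings, per-minute delivered insulin, and a time-ordered event log
#'   (basal, temp_basal, smb, meal, rescue).
#' @export
simulate_closed_loop <- function(pig, controller = c("oref1", "loop"),
                                 config = NULL,
                                 schedule = challenge_schedule(),
                                 sensor = cgm_sensor(),
                                 hours = 30, start_clock = 60,
                                 init_glucose = 120, seed = NULL) {
  stopifnot(inherits(pig, "pig_params"))
  controller <- match.arg(controller)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(config)) {
    config <- if (controller == "oref1") oref1_config() else loop_config()
  }
  # the pig's true absorption is always the fitted pig model; the Loop-style
  # controller *models* it with a 15-min onset (its own curve variant)
  curve <- if (controller == "oref1") pig_insulin_curve() else loop_insulin_curve()
  true_curve <- pig_insulin_curve()

  n <- round(hours * 60)
  kern <- sc_kernel(true_curve)
  margin <- max(length(kern), 240) + 300
  act_sc <- prewarm_sc(numeric(n + margin), pig$basal_rate, kern)
  act_iv <- numeric(n + margin)
  carbs <- numeric(n + margin)
  csf <- carb_sensitivity(pig)
  egp <- pig$isf * pig$basal_rate / 60
  settings <- list(basal = pig$basal_rate, isf = pig$isf)

  ev_time <- numeric(0); ev_kind <- character(0)
  ev_amount <- numeric(0); ev_unit <- character(0); ev_reason <- character(0)
  log_event <- function(t, kind, amount, unit, reason = "") {
    ev_time <<- c(ev_time, t); ev_kind <<- c(ev_kind, kind)
    ev_amount <<- c(ev_amount, amount); ev_unit <<- c(ev_unit, unit)
    ev_reason <<- c(ev_reason, reason)
  }
  log_event(0, "basal", pig$basal_rate, "U/h", "scheduled")

  # schedule the meals that fall inside the run
  for (m in schedule$meals) {
    tm <- m$time - start_clock
    if (tm >= 0 && tm < n) {
      carbs <- add_kernel(carbs, tm, m$grams, meal_kernel(m$profile))
      log_event(tm, "meal", m$grams, "g", m$profile)
    }
  }

  n_cycles <- n %/% 5 + 1
  cgm_time <- numeric(n_cycles); cgm_val <- numeric(n_cycles); n_cgm <- 0L
  dose_t <- numeric(0); dose_u <- numeric(0)   # controller-side net-of-basal log
  temp_rate <- NA_real_; temp_expiry <- -1
  last_rescue <- -Inf
  disc <- numeric(0)        # Loop: recent forecast discrepancies
  last_forecast <- NULL

  g <- numeric(n + 1); g[1] <- init_glucose
  delivered <- numeric(n)

  for (t in 0:(n - 1)) {
    if (t %% 5 == 0) {
      reading <- sample_cgm(g[t + 1], sensor)
      n_cgm <- n_cgm + 1L
      cgm_time[n_cgm] <- t; cgm_val[n_cgm] <- reading

      # rescue rule: two measures < 55, or CGM alone < 40
      if (t - last_rescue >= 30 &&
          rescue_check(reading, second_measure = g[t + 1])) {
        carbs <- add_kernel(carbs, t, 10, meal_kernel("fast"))
        log_event(t, "rescue", 10, "g", sprintf("cgm %.0f true %.0f", reading, g[t + 1]))
        last_rescue <- t
      }

      # fold the last cycle's temp-vs-scheduled delivery into the net log
      if (t > 0) {
        net <- sum(delivered[(t - 4):t]) - 5 * pig$basal_rate / 60
        if (abs(net) > 1e-12) {
          dose_t <- c(dose_t, t - 2); dose_u <- c(dose_u, net)
        }
      }
      keep <- (t - dose_t) < curve$dia
      dose_t <- dose_t[keep]; dose_u <- dose_u[keep]

      hist <- list(time = cgm_time[seq_len(n_cgm)], reading = cgm_val[seq_len(n_cgm)])
      if (controller == "oref1") {
        cmd <- oref1_decide(hist, dose_t, dose_u, curve, settings, config, now = t)
      } else {
        if (!is.null(last_forecast)) {
          disc <- c(disc, reading - last_forecast$predicted[2])
          if (length(disc) > config$n_stored_forecasts) {
            disc <- disc[-seq_len(length(disc) - config$n_stored_forecasts)]
          }
        }
        cmd <- loop_decide(hist, dose_t, dose_u, disc, curve, settings, config, now = t)
        last_forecast <- attr(cmd, "forecast")
      }

      if (!is.null(cmd$smb) && cmd$smb > 0) {
        act_sc <- add_kernel(act_sc, t, cmd$smb, kern)
        dose_t <- c(dose_t, t); dose_u <- c(dose_u, cmd$smb)
        log_event(t, "smb", cmd$smb, "U", cmd$reason)
      }
      if (!is.null(cmd$temp_basal)) {
        temp_rate <- cmd$temp_basal
        temp_expiry <- t + cmd$duration
        log_event(t, "temp_basal", cmd$temp_basal, "U/h", cmd$reason)
      }
    }

    rate_now <- if (!is.na(temp_rate) && t < temp_expiry) temp_rate else pig$basal_rate
    act_sc <- add_kernel(act_sc, t, rate_now / 60, kern)
    delivered[t + 1] <- rate_now / 60
    g[t + 2] <- max(GLUCOSE_FLOOR,
                    g[t + 1] - pig$isf * (act_sc[t + 1] + act_iv[t + 1]) +
                      csf * carbs[t + 1] + egp)
  }
  # account SMBs in total delivery at the minute they were given
  smb_idx <- ev_kind == "smb"
  if (any(smb_idx)) {
    ii <- ev_time[smb_idx] + 1
    delivered[ii] <- delivered[ii] + ev_amount[smb_idx]
  }

  structure(list(
    pig = pig, controller = controller, config = config, sensor = sensor,
    schedule = schedule, seed = seed, start_clock = start_clock,
    minutes = 0:n, clock = start_clock + 0:n,
    true_glucose = g,
    cgm = data.frame(time = cgm_time[seq_len(n_cgm)],
                     clock = start_clock + cgm_time[seq_len(n_cgm)],
                     reading = cgm_val[seq_len(n_cgm)]),
    delivered = delivered,
    events = data.frame(time = ev_time, clock = start_clock + ev_time,
                        kind = ev_kind, amount = ev_amount, unit = ev_unit,
                        reason = ev_reason, stringsAsFactors = FALSE)
  ), class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("Closed-loop trace: pig %s, %s controller, %d min, %d CGM readings\n",
              x$pig$id, x$controller, length(x$minutes) - 1, nrow(x$cgm)))
  cat(sprintf("  true glucose %0.f-%0.f mg/dl; %d events (%d rescues)\n",
              min(x$true_glucose), max(x$true_glucose), nrow(x$events),
              sum(x$events$kind == "rescue")))
  invisible(x)
}
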