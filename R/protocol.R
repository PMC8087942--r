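# The daily meal-challenge protocol: meal schedule, monitoring windows,
# rescue rule, per-window glycemic metrics, and cross-pig aggregation.

#' The daily meal-challenge schedule
#'
#' Three meals per day without announcements: breakfast at 07:30 (66 g fast
#' carbohydrate), lunch at 13:30 and dinner at 19:00 (132 g mixed meal
#' each). Four monitoring windows: the 6 h following breakfast, the 5 h
#' following lunch and dinner, and the 01:00-07:00 overnight window of the
#' following morning (so overnight reflects post-dinner carryover). Clock
#' times are minutes after midnight of the simulated day.
#'
#' @param breakfast_g,lunch_g,dinner_g carbohydrate grams per meal.
#' @return An object of class `challenge_schedule` with `meals` (list of
#'   [meal_event()]) and `windows` (data frame `label`, `start`, `end`).
#' @export
challenge_schedule <- function(breakfast_g = 66, lunch_g = 132, dinner_g = 132) {
  meals <- list(
    meal_event(450, breakfast_g, "fast"),    # 07:30
    meal_event(810, lunch_g, "mixed"),       # 13:30
    meal_event(1140, dinner_g, "mixed")      # 19:00
  )
  windows <- data.frame(
    label = c("breakfast", "lunch", "dinner", "overnight"),
    start = c(450, 810, 1140, 1500),
    end = c(810, 1110, 1440, 1860)
  )
  ord <- order(windows$start)
  if (any(windows$start[ord][-1] < windows$end[ord][-nrow(windows)])) {
    stop("monitoring windows overlap")
  }
  structure(list(meals = meals, windows = windows), class = "challenge_schedule")
}

#' Time-in-range
#'
#' Percentage of 5-min readings within `[lo, hi]` (bounds inclusive).
#'
#' @param readings glucose readings in the window, mg/dl.
#' @param lo,hi euglycemic range bounds, mg/dl.
#' @return Percent, in `[0, 100]`.
#' @export
time_in_range <- function(readings, lo = 70, hi = 180) {
  if (length(readings) == 0) stop("no readings in window; TIR is undefined")
  100 * mean(readings >= lo & readings <= hi)
}

#' Time below threshold
#'
#' Percentage of 5-min readings strictly below `thresh` (a reading exactly
#' at the threshold is not counted).
#'
#' @param readings glucose readings in the window, mg/dl.
#' @param thresh hypoglycemia threshold, mg/dl.
#' @return Percent, in `[0, 100]`.
#' @export
time_below <- function(readings, thresh = 70) {
  if (length(readings) == 0) stop("no readings in window; metric is undefined")
  100 * mean(readings < thresh)
}

#' Time above threshold
#'
#' Percentage of 5-min readings strictly above `hi`. Together with
#' [time_in_range()] and [time_below()] this partitions the window:
#' the three percentages sum to 100.
#'
#' @param readings glucose readings in the window, mg/dl.
#' @param hi hyperglycemia threshold, mg/dl.
#' @return Percent, in `[0, 100]`.
#' @export
time_above <- function(readings, hi = 180) {
  if (length(readings) == 0) stop("no readings in window; metric is undefined")
  100 * mean(readings > hi)
}

#' Corrective-carbohydrate rule
#'
#' Rescue carbohydrates are indicated when two independent glucose measures
#' (e.g. CGM plus an ear-prick or blood draw) are both below 55 mg/dl, or
#' when the CGM alone reads below 40 mg/dl. A CGM value just under 55 with
#' no confirmatory measure does not trigger a rescue.
#'
#' @param cgm CGM reading, mg/dl.
#' @param second_measure confirmatory measurement, mg/dl, or `NULL`/`NA` if
#'   absent.
#' @return `TRUE` if corrective carbohydrates (10 g fast sugar) are
#'   indicated.
#' @export
rescue_check <- function(cgm, second_measure = NULL) {
  if (cgm < 40) return(TRUE)
  if (cgm < 55 && !is.null(second_measure) && !is.na(second_measure) &&
      second_measure < 55) {
    return(TRUE)
  }
  FALSE
}

#' Per-window glycemic metrics of a trace
#'
#' Scores each monitoring window of a [simulate_closed_loop()] trace from
#' its 5-min CGM readings: time-in-range 70-180, time below 70, time above
#' 180, a severe-hypoglycemia flag (a rescue event occurred in the window),
#' and the insulin delivered. Windows whose CGM trace has a gap longer than
#' 60 min are marked invalid.
#'
#' @param trace a `sim_trace`.
#' @param max_gap longest tolerated CGM gap before a window is excluded,
#'   minutes.
#' @return Data frame with one row per window: `pig`, `controller`, `meal`,
#'   `tir`, `below70`, `above180`, `severe`, `insulin_u`, `n_intervals`,
#'   `valid`.
#' @export
window_metrics <- function(trace, max_gap = 60) {
  stopifnot(inherits(trace, "sim_trace"))
  win <- trace$schedule$windows
  out <- lapply(seq_len(nrow(win)), function(i) {
    inw <- trace$cgm$clock >= win$start[i] & trace$cgm$clock < win$end[i]
    r <- trace$cgm$reading[inw]
    tt <- trace$cgm$time[inw]
    gaps <- if (length(tt) > 1) max(diff(tt)) else Inf
    span_ok <- length(tt) > 0 &&
      (tt[1] - (win$start[i] - trace$start_clock)) <= max_gap
    rescue_in <- any(trace$events$kind == "rescue" &
                       trace$events$clock >= win$start[i] &
                       trace$events$clock < win$end[i])
    mins <- trace$clock[-length(trace$clock)]   # minute i covers clock[i]..+1
    ins <- sum(trace$delivered[mins >= win$start[i] & mins < win$end[i]])
    data.frame(
      pig = trace$pig$id, controller = trace$controller, meal = win$label[i],
      tir = if (length(r)) time_in_range(r) else NA_real_,
      below70 = if (length(r)) time_below(r) else NA_real_,
      above180 = if (length(r)) time_above(r) else NA_real_,
      severe = rescue_in,
      insulin_u = ins,
      n_intervals = length(r),
      valid = length(r) > 0 && gaps <= max_gap && span_ok,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Run the full closed-loop meal challenge
#'
#' Simulates each pig for `days` independent pig-days under the chosen
#' controller (each pig-day spans 01:00 to 07:00 the next morning and is
#' scored over the breakfast, lunch, dinner and following-overnight
#' windows), then aggregates per-window metrics across pigs. Pig-day RNG
#' seeds are enumerated from `seed` (`seed`, `seed + 1`, ...) so a run is
#' fully reproducible.
#'
#' @param pigs list of [pig_params()] (default [study_pigs()]).
#' @param controller `"oref1"` or `"loop"`.
#' @param days pig-days per pig.
#' @param seed base RNG seed.
#' @param config,schedule,sensor passed to [simulate_closed_loop()].
#' @param keep_traces retain the full traces in the result.
#' @return A list of class `challenge_result`: `results` (one row per pig x
#'   day x window), `aggregate` (per controller x window mean and SE across
#'   pigs, pigs first averaged over their days), and optionally `traces`.
#' @export
run_challenge <- function(pigs = study_pigs(), controller = c("oref1", "loop"),
                          days = 3, seed = 1, config = NULL,
                          schedule = challenge_schedule(),
                          sensor = cgm_sensor(), keep_traces = FALSE) {
  controller <- match.arg(controller)
  idx <- 0L
  rows <- list()
  traces <- list()
  for (pig in pigs) {
    for (day in seq_len(days)) {
      idx <- idx + 1L
      tr <- simulate_closed_loop(pig, controller, config = config,
                                 schedule = schedule, sensor = sensor,
                                 seed = seed + idx - 1L)
      wm <- window_metrics(tr)
      wm$day <- day
      rows[[idx]] <- wm
      if (keep_traces) traces[[idx]] <- tr
    }
  }
  results <- do.call(rbind, rows)
  structure(list(results = results, aggregate = aggregate_challenge(results),
                 traces = if (keep_traces) traces else NULL,
                 controller = controller, days = days, seed = seed),
            class = "challenge_result")
}

#' Aggregate challenge results across pigs
#'
#' Pig-first averaging: each pig's windows are first averaged over its days,
#' then the mean and standard error are taken across pigs, per controller
#' and monitoring window. Invalid (gap-excluded) windows are dropped first;
#' empty cells are omitted with a warning.
#'
#' @param results the `results` data frame of [run_challenge()] (or any data
#'   frame with `pig`, `controller`, `meal`, `tir`, `below70`, `insulin_u`,
#'   `valid`).
#' @return Data frame per (controller, meal): `mean_tir`, `se_tir`,
#'   `mean_below70`, `se_below70`, `mean_insulin_u`, `se_insulin_u`,
#'   `n_pigs`.
#' @export
aggregate_challenge <- function(results) {
  res <- results[results$valid, , drop = FALSE]
  if (nrow(res) == 0) stop("no valid windows to aggregate")
  pig_means <- stats::aggregate(
    res[, c("tir", "below70", "insulin_u")],
    by = list(controller = res$controller, meal = res$meal, pig = res$pig),
    FUN = mean
  )
  cells <- unique(pig_means[, c("controller", "meal")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- pig_means[pig_means$controller == cells$controller[i] &
                        pig_means$meal == cells$meal[i], , drop = FALSE]
    se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
    data.frame(
      controller = cells$controller[i], meal = cells$meal[i],
      mean_tir = mean(cell$tir), se_tir = se(cell$tir),
      mean_below70 = mean(cell$below70), se_below70 = se(cell$below70),
      mean_insulin_u = mean(cell$insulin_u), se_insulin_u = se(cell$insulin_u),
      n_pigs = nrow(cell), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  all_meals <- c("breakfast", "lunch", "dinner", "overnight")
  missing <- setdiff(all_meals, out$meal)
  if (length(missing)) {
    warning("no valid results for window(s): ", paste(missing, collapse = ", "))
  }
  out[order(out$controller, match(out$meal, all_meals)), ]
}

#' @export
print.challenge_result <- function(x, ...) {
  cat(sprintf("Meal challenge: %s controller, %d pig(s) x %d day(s), seed %s\n",
              x$controller, length(unique(x$results$pig)), x$days, x$seed))
  print(x$aggregate, row.names = FALSE, digits = 3)
  invisible(x)
}
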