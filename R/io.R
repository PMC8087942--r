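# CSV formats and run configuration. Glucose is always mg/dl, insulin U,
# carbohydrates g; timestamps are ISO-8601 UTC. Every output file carries
# `# key: value` header comments recording the seed and configuration hash
# that produced it.

iso_time <- function(clock_min, base_date = "2026-01-01") {
  as.POSIXct(base_date, tz = "UTC") + clock_min * 60
}

#' Hash a configuration object
#'
#' Stable content hash used to stamp output files with the configuration
#' that produced them.
#'
#' @param x any R object.
#' @return Character hash.
#' @export
config_hash <- function(x) rlang::hash(x)

write_csv_with_header <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Write a simulation trace to CSV
#'
#' Writes two files: a readings CSV (`timestamp`, `glucose`) and an events
#' CSV (`timestamp`, `kind`, `amount`, `unit`, `reason`), both with `# seed`
#' and `# config_hash` header comments.
#'
#' @param trace a `sim_trace` from [simulate_closed_loop()].
#' @param readings_path,events_path output paths.
#' @param base_date calendar date mapped to clock minute 0.
#' @return Invisibly, the two paths.
#' @export
write_trace <- function(trace, readings_path, events_path,
                        base_date = "2026-01-01") {
  stopifnot(inherits(trace, "sim_trace"))
  meta <- list(seed = if (is.null(trace$seed)) "none" else trace$seed,
               config_hash = config_hash(trace[c("config", "sensor", "schedule")]))
  readings <- data.frame(
    timestamp = format(iso_time(trace$cgm$clock, base_date),
                       "%Y-%m-%dT%H:%M:%SZ"),
    glucose = round(trace$cgm$reading, 2)
  )
  events <- data.frame(
    timestamp = format(iso_time(trace$events$clock, base_date),
                       "%Y-%m-%dT%H:%M:%SZ"),
    kind = trace$events$kind, amount = trace$events$amount,
    unit = trace$events$unit, reason = trace$events$reason
  )
  write_csv_with_header(readings, readings_path, meta)
  write_csv_with_header(events, events_path, meta)
  invisible(c(readings_path, events_path))
}

#' Read a glucose readings CSV
#'
#' Expects a header (`timestamp`, `glucose`), ISO-8601 timestamps and
#' numeric mg/dl values; `#`-prefixed header comments are skipped. Unsorted
#' input is sorted with a warning; duplicate timestamps or malformed rows
#' are errors (reported with their line number).
#'
#' @param path path to the readings CSV.
#' @return Data frame with `timestamp` (POSIXct, UTC) and `glucose`.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#")
  offset <- which(body)[1]   # line number of the header row
  df <- utils::read.csv(text = lines[body], stringsAsFactors = FALSE)
  if (!all(c("timestamp", "glucose") %in% names(df))) {
    stop("expected columns 'timestamp' and 'glucose' in ", path)
  }
  ts <- as.POSIXct(df$timestamp, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
  glucose <- suppressWarnings(as.numeric(df$glucose))
  bad <- which(is.na(ts) | is.na(glucose))
  if (length(bad)) {
    stop("malformed row at line ", offset + bad[1], " of ", path)
  }
  if (anyDuplicated(ts)) {
    stop("duplicate timestamp at line ",
         offset + which(duplicated(ts))[1], " of ", path)
  }
  if (is.unsorted(ts)) {
    warning("readings were not time-ordered; sorting")
    ord <- order(ts)
    ts <- ts[ord]; glucose <- glucose[ord]
  }
  data.frame(timestamp = ts, glucose = glucose)
}

#' Read and validate a run configuration
#'
#' YAML key-value configuration for a simulation run. Recognised keys:
#' `pigs` (list of `id`/`basal_rate`/`isf`/`icr` records; default the study
#' herd), `controller` (`oref1`/`loop`), `days`, `seed`, `hours`, `out_dir`,
#' `sensor` (overrides for [cgm_sensor()]), `oref1` / `loop` (controller
#' overrides), `schedule` (meal-gram overrides). Unknown keys are rejected.
#'
#' @param path path to the YAML file.
#' @return A validated named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("pigs", "controller", "days", "seed", "hours", "out_dir",
               "sensor", "oref1", "loop", "schedule")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  pigs <- if (is.null(raw$pigs)) study_pigs() else {
    lapply(raw$pigs, function(p) {
      pig_params(p$id, p$basal_rate, p$isf, p$icr)
    })
  }
  controller <- if (is.null(raw$controller)) "oref1" else
    match.arg(raw$controller, c("oref1", "loop"))
  sensor <- do.call(cgm_sensor, if (is.null(raw$sensor)) list() else raw$sensor)
  schedule <- do.call(challenge_schedule,
                      if (is.null(raw$schedule)) list() else raw$schedule)
  config <- if (controller == "oref1") {
    do.call(oref1_config, if (is.null(raw$oref1)) list() else raw$oref1)
  } else {
    do.call(loop_config, if (is.null(raw$loop)) list() else raw$loop)
  }
  list(pigs = pigs, controller = controller,
       days = if (is.null(raw$days)) 3L else as.integer(raw$days),
       seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
       hours = if (is.null(raw$hours)) 30 else as.numeric(raw$hours),
       out_dir = if (is.null(raw$out_dir)) "." else raw$out_dir,
       sensor = sensor, schedule = schedule, config = config)
}

#' Write challenge results and aggregate tables
#'
#' One row per pig x day x window in the results CSV; one row per
#' (controller, window) in the aggregate CSV. Both are stamped with the
#' seed and configuration hash.
#'
#' @param challenge a `challenge_result` from [run_challenge()].
#' @param results_path,aggregate_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_challenge <- function(challenge, results_path, aggregate_path) {
  stopifnot(inherits(challenge, "challenge_result"))
  meta <- list(seed = challenge$seed,
               config_hash = config_hash(challenge[c("controller", "days")]))
  write_csv_with_header(challenge$results, results_path, meta)
  write_csv_with_header(challenge$aggregate, aggregate_path, meta)
  invisible(c(results_path, aggregate_path))
}
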