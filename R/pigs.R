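#' Virtual pig dosing parameters
#'
#' A virtual pig is defined by the three individually titrated dosing
#' parameters used to configure a closed-loop system: the basal rate that
#' holds fasted glucose steady, the insulin sensitivity factor (ISF, the
#' glucose drop per unit of insulin) and the insulin-to-carbohydrate ratio
#' (ICR, grams of carbohydrate covered per unit).
#'
#' @param id label for the pig.
#' @param basal_rate basal insulin requirement, U/h; must lie in (0, 5].
#' @param isf insulin sensitivity factor, mg/dl per U; > 0.
#' @param icr insulin-to-carbohydrate ratio, g per U; > 0.
#' @return An object of class `pig_params`.
#' @export
pig_params <- function(id, basal_rate, isf, icr) {
  stopifnot(length(basal_rate) == 1, length(isf) == 1, length(icr) == 1)
  if (!(basal_rate > 0 && basal_rate <= 5)) stop("basal_rate must be in (0, 5] U/h")
  if (!(isf > 0)) stop("isf must be positive")
  if (!(icr > 0)) stop("icr must be positive")
  structure(list(id = as.character(id), basal_rate = basal_rate,
                 isf = isf, icr = icr),
            class = "pig_params")
}

#' @export
print.pig_params <- function(x, ...) {
  cat(sprintf("Virtual pig %s: basal %.2f U/h, ISF %g mg/dl/U, ICR %g g/U\n",
              x$id, x$basal_rate, x$isf, x$icr))
  invisible(x)
}

#' The default herd of six calibrated virtual pigs
#'
#' Dosing parameters of the six insulin-deficient study animals, determined
#' in vivo by overnight basal titration, an intravenous 1 U ISF test and
#' mealtime bolus titration. Basal requirements span 0.10-0.30 U/h and ISF
#' spans 110-167 mg/dl per unit; ICR is carried for the carbohydrate
#' sensitivity identity even though neither controller uses it without meal
#' announcements.
#'
#' @return A list of six [pig_params()] objects.
#' @export
study_pigs <- function() {
  tab <- data.frame(
    id = as.character(1:6),
    basal_rate = c(0.15, 0.20, 0.10, 0.30, 0.20, 0.25),
    isf = c(110, 167, 154, 158, 160, 132),
    icr = c(49, 90, 68, 59, 69, 58)
  )
  lapply(seq_len(nrow(tab)), function(i) {
    pig_params(tab$id[i], tab$basal_rate[i], tab$isf[i], tab$icr[i])
  })
}

#' Carbohydrate sensitivity factor
#'
#' Glucose rise per gram of carbohydrate, from the standard identity
#' CSF = ISF / ICR.
#'
#' @param pig a [pig_params()] object.
#' @return mg/dl per g.
#' @export
carb_sensitivity <- function(pig) {
  stopifnot(inherits(pig, "pig_params"))
  pig$isf / pig$icr
}

#' Meal event
#'
#' @param time clock time of the meal, minutes after midnight.
#' @param grams grams of carbohydrate (>= 0).
#' @param profile absorption profile: `"fast"` (simple sugars, complete by
#'   2 h) or `"mixed"` (mixed meal, complete by 4 h).
#' @return An object of class `meal_event`.
#' @export
meal_event <- function(time, grams, profile = c("fast", "mixed")) {
  profile <- match.arg(profile)
  if (grams < 0) stop("grams must be >= 0")
  structure(list(time = time, grams = grams, profile = profile),
            class = "meal_event")
}

#' CGM sensor model
#'
#' A continuous glucose monitor sampling the true glucose every `interval`
#' minutes with additive Gaussian noise and a constant bias, clamped to the
#' reportable range. The default slightly negative bias reflects the
#' device's tendency to under-read in this species.
#'
#' @param interval sampling interval, minutes.
#' @param noise_sd standard deviation of the reading noise, mg/dl.
#' @param bias constant reading offset, mg/dl.
#' @param floor,ceiling reportable range, mg/dl.
#' @return An object of class `cgm_sensor`.
#' @export
cgm_sensor <- function(interval = 5, noise_sd = 5, bias = -3,
                       floor = 40, ceiling = 400) {
  if (!(interval > 0)) stop("interval must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!(floor < ceiling)) stop("floor must be below ceiling")
  structure(list(interval = interval, noise_sd = noise_sd, bias = bias,
                 floor = floor, ceiling = ceiling),
            class = "cgm_sensor")
}

#' Sample a CGM reading
#'
#' `reading = clamp(glucose + bias + N(0, noise_sd), floor, ceiling)`.
#' Randomness comes from R's global RNG; seed it (`set.seed()`) for
#' reproducible traces.
#'
#' @param glucose true glucose, mg/dl (vectorised).
#' @param sensor a [cgm_sensor()].
#' @return Reading(s), mg/dl.
#' @export
sample_cgm <- function(glucose, sensor) {
  stopifnot(inherits(sensor, "cgm_sensor"), all(glucose > 0))
  noise <- if (sensor$noise_sd > 0) {
    stats::rnorm(length(glucose), 0, sensor$noise_sd)
  } else {
    0
  }
  pmin(pmax(glucose + sensor$bias + noise, sensor$floor), sensor$ceiling)
}
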