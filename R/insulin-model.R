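#' Exponential insulin action curve
#'
#' Constructs the two-parameter exponential insulin activity model used by
#' open-source automated insulin delivery systems, optionally shifted by an
#' onset delay. The curve is parameterised by the time of peak activity
#' (`tpa`) and the total duration of insulin action (`dia`), both measured in
#' minutes from the injection. Activity is zero outside `(delay, dia)`,
#' unimodal with its maximum at `tpa`, and integrates to one over the duration
#' of action, so it can be read as the fraction of a dose acting per minute.
#'
#' With `td = dia - delay`, `tp = tpa - delay` and `s = t - delay`, the model
#' is
#' \deqn{\tau = tp (1 - tp/td) / (1 - 2 tp/td), \quad a = 2\tau/td, \quad
#'       S = 1 / (1 - a + (1 + a) e^{-td/\tau}),}
#' \deqn{activity(s) = (S/\tau^2)\, s (1 - s/td)\, e^{-s/\tau}.}
#' The parameterisation requires `tp < td/2`; at `tp = td/2` the scale
#' \eqn{\tau} diverges.
#'
#' @param delay onset lag in minutes (activity is exactly zero up to this
#'   time); `0` for the pig model as used by the oref1-style controller,
#'   `15` for the Loop variant.
#' @param tpa time of peak activity in minutes after injection.
#' @param dia total duration of insulin action in minutes after injection.
#' @return An object of class `insulin_curve`.
#' @examples
#' crv <- insulin_action_curve(0, 25, 180)
#' insulin_activity(crv, c(0, 25, 180))
#' insulin_iob(crv, c(0, 90, 180))
#' @export
insulin_action_curve <- function(delay = 0, tpa = 25, dia = 180) {
  stopifnot(is.numeric(delay), is.numeric(tpa), is.numeric(dia),
            length(delay) == 1, length(tpa) == 1, length(dia) == 1)
  if (delay < 0) stop("onset delay must be >= 0")
  if (!(delay < tpa)) stop("time of peak activity must exceed the onset delay")
  if (!(tpa < dia)) stop("duration of action must exceed the time of peak activity")
  td <- dia - delay
  tp <- tpa - delay
  if (!(tp < td / 2)) {
    stop("invalid parameterization: peak must occur before half of the ",
         "(delay-adjusted) duration of action, i.e. (tpa - delay) < (dia - delay)/2")
  }
  tau <- tp * (1 - tp / td) / (1 - 2 * tp / td)
  a <- 2 * tau / td
  S <- 1 / (1 - a + (1 + a) * exp(-td / tau))
  structure(
    list(delay = delay, tpa = tpa, dia = dia, td = td, tau = tau, a = a, S = S),
    class = "insulin_curve"
  )
}

#' @export
print.insulin_curve <- function(x, ...) {
  cat(sprintf("Insulin action curve: onset %g min, peak %g min, duration %g min\n",
              x$delay, x$tpa, x$dia))
  invisible(x)
}

#' Insulin activity at time t
#'
#' Fraction of a subcutaneous dose acting per minute, `t` minutes after
#' injection. Vectorised over `t`.
#'
#' @param curve an [insulin_action_curve()].
#' @param t minutes since injection (vector allowed; values beyond the
#'   duration of action return 0).
#' @return Activity in fraction of dose per minute.
#' @export
insulin_activity <- function(curve, t) {
  stopifnot(inherits(curve, "insulin_curve"))
  s <- t - curve$delay
  out <- numeric(length(t))
  inside <- s > 0 & s < curve$td
  si <- s[inside]
  out[inside] <- (curve$S / curve$tau^2) * si * (1 - si / curve$td) *
    exp(-si / curve$tau)
  out
}

#' Insulin on board at time t
#'
#' Fraction of a dose not yet acted, `t` minutes after injection:
#' `iob(t) = 1 - integral of activity over [0, t]`, available in closed form
#' for the exponential model. `iob(0) = 1`, `iob(t >= dia) = 0`, and the
#' function is non-increasing. Vectorised over `t`.
#'
#' @inheritParams insulin_activity
#' @return Fraction of dose remaining, in `[0, 1]`.
#' @export
insulin_iob <- function(curve, t) {
  stopifnot(inherits(curve, "insulin_curve"))
  s <- t - curve$delay
  out <- numeric(length(t))
  out[s <= 0] <- 1
  inside <- s > 0 & s < curve$td
  si <- s[inside]
  tau <- curve$tau; td <- curve$td; a <- curve$a; S <- curve$S
  val <- 1 - S * (1 - a) *
    ((si^2 / (tau * td * (1 - a)) - si / tau - 1) * exp(-si / tau) + 1)
  out[inside] <- pmin(1, pmax(0, val))
  out
}

#' Pig insulin model presets
#'
#' The insulin action model fitted for diabetic pigs, whose lispro
#' pharmacokinetics are faster than in humans: peak activity at 25 min and a
#' 3 h duration of action (the duration is deliberately generous relative to
#' the ~2 h exposure, to avoid under-counting insulin on board and stacking
#' doses). `loop_insulin_curve()` is the same model with the 15-min onset lag
#' used by the Loop-style controller, which models no glucose-lowering effect
#' before 15 min.
#'
#' @return An [insulin_action_curve()].
#' @export
pig_insulin_curve <- function() insulin_action_curve(0, 25, 180)

#' @rdname pig_insulin_curve
#' @export
loop_insulin_curve <- function() insulin_action_curve(15, 25, 180)

#' Fit the action curve to pharmacokinetic samples
#'
#' Least-squares fit of the scaled activity shape `A * activity(t; tpa, dia)`
#' to plasma insulin concentration-time samples, with the onset delay held
#' fixed (0 for the oref1-style variant, 15 min for the Loop variant) and
#' `tpa` and `dia` free. To keep the exponential parameterisation valid
#' during optimisation the curve is fitted in terms of `tpa` and the ratio
#' `r = (tpa - delay)/(dia - delay)`, box-bounded to `(0, 0.5)`;
#' Levenberg-Marquardt least squares via [minpack.lm::nls.lm()].
#'
#' @param samples data frame with columns `time` (minutes since injection)
#'   and `concentration` (arbitrary units, e.g. mU/L).
#' @param delay onset delay in minutes, held fixed.
#' @param start optional named list of starting values (`tpa`, `dia`).
#' @return A list with elements `curve` (the fitted [insulin_action_curve()]),
#'   `scale` (the fitted amplitude), `rss` (residual sum of squares) and
#'   `residuals`.
#' @export
fit_action_curve <- function(samples, delay = 0, start = NULL) {
  stopifnot(is.data.frame(samples),
            all(c("time", "concentration") %in% names(samples)))
  tt <- as.numeric(samples$time)
  cc <- as.numeric(samples$concentration)
  if (anyNA(tt) || anyNA(cc)) stop("samples contain missing values")
  if (any(tt < 0) || any(cc < 0)) stop("times and concentrations must be nonnegative")
  if (length(unique(tt)) < 5) stop("need at least 5 distinct sample times spanning the peak")
  if (all(cc == 0)) stop("all concentrations are zero; nothing to fit")

  t_peak <- tt[which.max(cc)]
  tpa0 <- if (!is.null(start$tpa)) start$tpa else max(t_peak, delay + 5)
  dia0 <- if (!is.null(start$dia)) start$dia else max(3.5 * (tpa0 - delay) + delay, max(tt))
  r0 <- min(0.45, max(0.05, (tpa0 - delay) / (dia0 - delay)))
  A0 <- max(cc) / max(insulin_activity(insulin_action_curve(delay, tpa0, dia0), tt))

  resid_fn <- function(p) {
    tpa <- p[["tpa"]]
    dia <- delay + (tpa - delay) / p[["r"]]
    crv <- insulin_action_curve(delay, tpa, dia)
    cc - p[["A"]] * insulin_activity(crv, tt)
  }
  fit <- minpack.lm::nls.lm(
    par = c(A = A0, tpa = tpa0, r = r0),
    lower = c(A = 1e-9, tpa = delay + 1, r = 0.02),
    upper = c(A = Inf, tpa = delay + 120, r = 0.48),
    fn = resid_fn
  )
  p <- fit$par
  dia_hat <- delay + (p[["tpa"]] - delay) / p[["r"]]
  list(
    curve = insulin_action_curve(delay, p[["tpa"]], dia_hat),
    scale = unname(p[["A"]]),
    rss = sum(fit$fvec^2),
    residuals = fit$fvec
  )
}

#' Read pharmacokinetic samples from CSV
#'
#' Two-column CSV (`time` in minutes, `concentration` in arbitrary units),
#' header required.
#'
#' @param path path to the CSV file.
#' @return data frame with columns `time`, `concentration`.
#' @export
read_pk_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected a two-column CSV with a header")
  names(df)[1:2] <- c("time", "concentration")
  if (!is.numeric(df$time) || !is.numeric(df$concentration)) {
    stop("time and concentration columns must be numeric")
  }
  df[, c("time", "concentration")]
}
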