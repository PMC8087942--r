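# Quadrature oracle for the insulin model: trapezoid rule on a fine grid,
# independent of the closed-form IOB expression.
quad_activity <- function(curve, upto, dt = 0.01) {
  g <- seq(0, upto, by = dt)
  a <- insulin_activity(curve, g)
  sum((a[-1] + a[-length(a)]) / 2) * dt
}

# Dose-bookkeeping oracle for forecast terminal values: explicit per-dose sum.
bookkeeping_terminal <- function(current_bg, dose_t, dose_u, curve, isf, now, horizon) {
  drop <- sum(dose_u * (insulin_iob(curve, now - dose_t) -
                          insulin_iob(curve, now - dose_t + horizon)))
  current_bg - isf * drop
}

# flat CGM history at 5-min spacing ending at `now`
flat_history <- function(bg, n = 8, now = (n - 1) * 5) {
  list(time = seq(now - (n - 1) * 5, now, by = 5), reading = rep(bg, n))
}

empty_doses <- list(time = numeric(0), units = numeric(0))
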