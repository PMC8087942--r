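test_that("the challenge schedule has the stated windows", {
  sch <- challenge_schedule()
  w <- sch$windows
  expect_equal(w$end - w$start, c(360, 300, 300, 360))
  expect_equal(w$label, c("breakfast", "lunch", "dinner", "overnight"))
  ord <- order(w$start)
  expect_true(all(w$start[ord][-1] >= w$end[ord][-4]))
  grams <- vapply(sch$meals, function(m) m$grams, numeric(1))
  expect_equal(grams, c(66, 132, 132))
  expect_equal(vapply(sch$meals, function(m) m$profile, character(1)),
               c("fast", "mixed", "mixed"))
})

test_that("range metrics count inclusively in-range and strictly below", {
  expect_equal(time_in_range(rep(100, 20)), 100)
  expect_equal(time_in_range(rep(250, 20)), 0)
  expect_equal(time_in_range(c(rep(100, 36), rep(250, 36))), 50)
  expect_equal(time_in_range(c(70, 180)), 100)   # bounds inclusive
  expect_equal(time_below(rep(100, 10)), 0)
  expect_equal(time_below(70), 0)                # exactly 70 is not below
  expect_equal(time_below(c(rep(65, 6), rep(100, 54))), 10)
  expect_error(time_in_range(numeric(0)), "undefined")
  expect_error(time_below(numeric(0)), "undefined")
})

test_that("TIR, below-70 and above-180 partition every window", {
  set.seed(77)
  for (i in 1:20) {
    r <- runif(72, 30, 350)
    expect_equal(time_in_range(r) + time_below(r) + time_above(r), 100)
  }
})

test_that("the rescue rule needs two low measures or a very low CGM alone", {
  expect_true(rescue_check(50, 50))
  expect_false(rescue_check(50, NULL))
  expect_false(rescue_check(50, 60))
  expect_true(rescue_check(38))
  expect_false(rescue_check(55, 54))     # CGM must be strictly below 55
  expect_true(rescue_check(54.9, 54.9))
})

test_that("a rescue injects 10 g and is refractory for 30 min", {
  pig <- study_pigs()[[1]]
  sch <- challenge_schedule(); sch$meals <- list()
  tr <- simulate_closed_loop(pig, "oref1", schedule = sch,
                             sensor = cgm_sensor(noise_sd = 0, bias = 0),
                             hours = 2, init_glucose = 45, seed = 1)
  rescues <- tr$events[tr$events$kind == "rescue", ]
  expect_gte(nrow(rescues), 1)
  expect_true(all(rescues$amount == 10))
  expect_true(all(rescues$unit == "g"))
  if (nrow(rescues) > 1) expect_true(all(diff(rescues$time) >= 30))
  # the carbohydrates act: glucose recovers above the rescue threshold
  expect_gt(max(tr$true_glucose), 55)
})

test_that("window metrics score each monitoring window from its readings", {
  pig <- study_pigs()[[6]]
  tr <- simulate_closed_loop(pig, "oref1", seed = 42)
  wm <- window_metrics(tr)
  expect_equal(nrow(wm), 4)
  expect_equal(wm$n_intervals, c(72, 60, 60, 72))
  expect_true(all(wm$valid))
  expect_true(all(abs(wm$tir + wm$below70 + wm$above180 - 100) < 1e-9))
  expect_true(all(wm$insulin_u > 0))
  # severe flags only where a rescue event fell inside the window
  expect_equal(wm$severe, vapply(seq_len(4), function(i) {
    any(tr$events$kind == "rescue" &
          tr$events$clock >= tr$schedule$windows$start[i] &
          tr$events$clock < tr$schedule$windows$end[i])
  }, logical(1)))
})

test_that("windows with CGM gaps over an hour are excluded", {
  pig <- study_pigs()[[1]]
  tr <- simulate_closed_loop(pig, "oref1", hours = 30, seed = 3)
  # knock out 70 min of readings inside the lunch window
  drop <- tr$cgm$clock >= 900 & tr$cgm$clock <= 970
  tr$cgm <- tr$cgm[!drop, ]
  wm <- window_metrics(tr)
  expect_false(wm$valid[wm$meal == "lunch"])
  expect_true(all(wm$valid[wm$meal != "lunch"]))
})

test_that("challenge runs emit one row per pig-day-window, reproducibly", {
  pigs <- study_pigs()[1:2]
  ch1 <- run_challenge(pigs, "oref1", days = 1, seed = 5)
  expect_equal(nrow(ch1$results), 2 * 1 * 4)
  ch2 <- run_challenge(pigs, "oref1", days = 1, seed = 5)
  expect_identical(ch1$results, ch2$results)
  expect_identical(ch1$aggregate, ch2$aggregate)
})

test_that("aggregation is pig-first with mean and standard error", {
  mk <- function(pig, day, tir) {
    data.frame(pig = pig, controller = "oref1", meal = "lunch", tir = tir,
               below70 = 0, above180 = 100 - tir, severe = FALSE,
               insulin_u = 1, n_intervals = 60, valid = TRUE, day = day)
  }
  # identical values: SE 0 (single-window fixtures warn about empty cells)
  agg0 <- suppressWarnings(aggregate_challenge(rbind(mk("a", 1, 80), mk("b", 1, 80))))
  expect_equal(agg0$se_tir, 0)
  # {80, 100} across two pigs: mean 90, SE 10
  agg1 <- suppressWarnings(aggregate_challenge(rbind(mk("a", 1, 80), mk("b", 1, 100))))
  expect_equal(agg1$mean_tir, 90)
  expect_equal(agg1$se_tir, 10)
  # a pig with three days still counts once
  agg2 <- suppressWarnings(aggregate_challenge(rbind(mk("a", 1, 100), mk("a", 2, 100),
                                    mk("a", 3, 100), mk("b", 1, 50))))
  expect_equal(agg2$mean_tir, 75)
  expect_equal(agg2$n_pigs, 2)
  # empty cells are dropped with a warning
  expect_warning(aggregate_challenge(mk("a", 1, 80)), "breakfast")
})
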