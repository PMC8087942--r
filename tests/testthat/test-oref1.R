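crv <- pig_insulin_curve()
cfg <- oref1_config()

test_that("deviations are observed change minus insulin-expected change", {
  # flat glucose, no insulin on board: all deviations zero
  h <- flat_history(120, n = 6)
  d <- compute_deviations(h, crv, isf = 130, empty_doses)
  expect_equal(d$deviation, rep(0, 5))

  # steady rise with no insulin: deviation equals the rise
  h2 <- list(time = seq(0, 25, by = 5), reading = 120 + seq(0, 25, by = 5))
  d2 <- compute_deviations(h2, crv, isf = 130, empty_doses)
  expect_equal(d2$deviation, rep(5, 5))

  # glucose exactly following insulin-only decline: zero deviations
  isf <- 130
  dose <- list(time = 0, units = 1)
  tt <- seq(0, 40, by = 5)
  bg <- 200 - isf * dose$units * (1 - insulin_iob(crv, tt))
  d3 <- compute_deviations(list(time = tt, reading = bg), crv, isf,
                           list(time = dose$time, units = dose$units))
  expect_equal(d3$deviation, rep(0, length(tt) - 1), tolerance = 1e-9)

  # a gap longer than 10 min is skipped as NA
  h4 <- list(time = c(0, 5, 20, 25), reading = c(120, 121, 119, 120))
  d4 <- compute_deviations(h4, crv, isf = 130, empty_doses)
  expect_true(is.na(d4$deviation[2]))
  expect_false(anyNA(d4$deviation[-2]))
})

test_that("insulin-only forecast matches the dose-bookkeeping oracle", {
  expect_equal(predict_iob(150, empty_doses, crv, 130, cfg, now = 0),
               rep(150, cfg$horizon / cfg$step + 1))
  # a 1 U dose just given decays fully within the horizon
  dl <- list(time = 0, units = 1)
  pred <- predict_iob(250, dl, crv, 130, cfg, now = 0)
  expect_equal(pred[length(pred)], 250 - 130, tolerance = 1e-9)
  # terminal value against the independent bookkeeping oracle
  dl2 <- list(time = c(-40, -10, 0), units = c(0.4, 0.3, 0.2))
  pred2 <- predict_iob(220, dl2, crv, 110, cfg, now = 0)
  expect_equal(pred2[length(pred2)],
               bookkeeping_terminal(220, dl2$time, dl2$units, crv, 110, 0, 240),
               tolerance = 1)
})

test_that("zero-temp forecast counts withheld basal as negative insulin", {
  none <- predict_zt(150, empty_doses, crv, 130, basal = 0, cfg, now = 0)
  expect_equal(none, rep(150, cfg$horizon / cfg$step + 1))
  dl <- list(time = 0, units = 1)
  zt <- predict_zt(250, dl, crv, 130, basal = 0.30, cfg, now = 0)
  iobp <- predict_iob(250, dl, crv, 130, cfg, now = 0)
  expect_true(all(zt >= iobp))
  # terminal difference equals the per-minute withheld-basal oracle
  withheld <- sum(1 - insulin_iob(crv, 1:240)) * 0.30 / 60
  expect_equal(zt[length(zt)] - iobp[length(iobp)], 130 * withheld,
               tolerance = 1e-9)
})

test_that("UAM extrapolation follows the three deviation cases", {
  K <- cfg$horizon / cfg$step
  iob_flat <- rep(150, K + 1)

  # peaked and falling at a reasonable rate: continue at that rate to zero
  u1 <- predict_uam(150, c(8, 6, 4), iob_flat, cfg)
  inc1 <- diff(u1 - iob_flat)
  expect_equal(inc1[1:3], c(2, 0, 0))
  expect_true(all(u1[4:(K + 1)] == u1[3]))

  # falling too slowly: forced linear decay reaching zero at 180 min
  u2 <- predict_uam(150, c(10.2, 10.1, 10), iob_flat, cfg)
  inc2 <- diff(u2 - iob_flat)
  expect_equal(inc2[1], 10 - 10 / 36, tolerance = 1e-9)
  expect_equal(inc2[36], 0, tolerance = 1e-9)       # zero from 180 min on
  expect_gt(inc2[35], 0)

  # still rising: immediate peak, decay at one-third the rise rate
  u3 <- predict_uam(150, c(0, 3, 6, 9), iob_flat, cfg)
  inc3 <- diff(u3 - iob_flat)
  expect_equal(inc3[1], 8, tolerance = 1e-9)        # 9 - 9/3 * 1... rate 1
  expect_equal(inc3[1] - inc3[2], 1, tolerance = 1e-9)
  expect_equal(u3[11:(K + 1)], rep(u3[10], K - 9))  # zero after 9/1 steps

  # all-zero deviations: UAM equals the insulin-only path
  expect_identical(predict_uam(150, c(0, 0, 0), iob_flat, cfg), iob_flat)
})

test_that("minPredBG is the stated max/average composition", {
  times <- seq(0, cfg$horizon, by = cfg$step)
  K <- length(times)
  flat <- function(v) rep(v, K)
  p0 <- list(iob = flat(150), zt = flat(150), uam = flat(150))
  expect_equal(min_pred_bg(p0, cfg), 150)

  iob <- flat(150); iob[times == 120] <- 120
  uam <- flat(160); uam[times == 90] <- 100
  zt <- flat(150); zt[1] <- 80
  expect_equal(min_pred_bg(list(iob = iob, zt = zt, uam = uam), cfg), 120)

  iob2 <- flat(150); iob2[times == 100] <- 90
  expect_equal(min_pred_bg(list(iob = iob2, zt = flat(120), uam = flat(140)),
                           cfg), 130)

  # minima before the scenario windows are ignored
  iob3 <- flat(150); iob3[times == 30] <- 50
  expect_equal(min_pred_bg(list(iob = iob3, zt = flat(150), uam = flat(150)),
                           cfg), 150)
})

test_that("insulinReq is (minPredBG - target)/ISF", {
  expect_equal(insulin_req(250, 120, 130), 1)
  expect_equal(insulin_req(120, 120, 130), 0)
  expect_equal(insulin_req(100, 120, 100), -0.2)
})

test_that("the SMB is capped by half the requirement, 30 min of basal, and IOB headroom", {
  settings <- list(basal = 0.30, isf = 100)
  # flat at 210, target 110, isf 100: insulinReq = 1.0 U
  cmd <- oref1_decide(flat_history(210), numeric(0), numeric(0), crv,
                      settings, oref1_config(target = 110), now = 35)
  expect_equal(cmd$insulin_req, 1, tolerance = 1e-9)
  expect_equal(cmd$smb, 0.15)        # 30 min of basal binds

  # maxIOB headroom binds
  cmd2 <- oref1_decide(flat_history(130), numeric(0), numeric(0), crv,
                       settings, oref1_config(target = 110, max_iob = 0.05),
                       now = 35)
  expect_equal(cmd2$insulin_req, 0.2, tolerance = 1e-9)
  expect_equal(cmd2$smb, 0.05)

  # half the requirement binds
  cmd3 <- oref1_decide(flat_history(130), numeric(0), numeric(0), crv,
                       settings, oref1_config(target = 110), now = 35)
  expect_equal(cmd3$smb, 0.10)       # min(0.1, 0.15, 2) rounded to 0.05 grid

  # negative requirement: no SMB, zero temp basal
  cmd4 <- oref1_decide(flat_history(60), numeric(0), numeric(0), crv,
                       settings, oref1_config(target = 110), now = 35)
  expect_lt(cmd4$insulin_req, 0)
  expect_equal(cmd4$smb, 0)
  expect_equal(cmd4$temp_basal, 0)
  expect_equal(cmd4$duration, 30)
})

test_that("at target with no IOB and no deviations the controller is a fixed point", {
  settings <- list(basal = 0.20, isf = 120)
  cmd <- oref1_decide(flat_history(110), numeric(0), numeric(0), crv,
                      settings, oref1_config(target = 110), now = 35)
  expect_equal(cmd$smb, 0)
  expect_equal(cmd$temp_basal, settings$basal, tolerance = 1e-9)
})

test_that("SMB cap invariants hold across random scenarios", {
  set.seed(1234)
  settings <- list(basal = 0.25, isf = 120)
  for (i in 1:30) {
    bg <- runif(1, 50, 350)
    readings <- bg + cumsum(c(0, rnorm(7, 0, 4)))
    h <- list(time = seq(0, 35, by = 5), reading = pmax(45, readings))
    nd <- sample(0:3, 1)
    dt <- sort(runif(nd, 0, 30)); du <- runif(nd, 0, 0.5)
    cmd <- oref1_decide(h, dt, du, crv, settings, cfg, now = 35)
    if (cmd$insulin_req > 0) {
      expect_lte(cmd$smb, cmd$insulin_req / 2 + 1e-9)
    }
    expect_lte(cmd$smb, settings$basal / 2 + 1e-9)
    expect_gte(cmd$smb, 0)
    expect_gte(cmd$temp_basal, 0)
    expect_lte(cmd$temp_basal, cfg$max_temp_basal)
  }
})

test_that("raising the target never increases the recommended insulin", {
  settings <- list(basal = 0.30, isf = 100)
  h <- flat_history(180)
  targets <- c(90, 110, 130, 150)
  doses <- vapply(targets, function(tg) {
    cmd <- oref1_decide(h, numeric(0), numeric(0), crv, settings,
                        oref1_config(target = tg), now = 35)
    cmd$smb + cmd$temp_basal / 2
  }, numeric(1))
  expect_true(all(diff(doses) <= 1e-9))
})

test_that("closed-loop commands never push IOB past the max_iob cap", {
  pig <- study_pigs()[[1]]
  sch <- challenge_schedule(); sch$meals <- list()
  tr <- simulate_closed_loop(pig, "oref1", schedule = sch,
                             sensor = cgm_sensor(noise_sd = 0, bias = 0),
                             hours = 8, init_glucose = 400, seed = 1)
  net <- tr$delivered - pig$basal_rate / 60
  for (t in seq(5, length(net), by = 5)) {
    iobt <- sum(net[seq_len(t)] * insulin_iob(crv, t - (seq_len(t) - 1)))
    expect_lte(iobt, oref1_config()$max_iob + 0.01)
  }
  # and the controller brings severe hyperglycemia to target
  expect_lt(abs(tail(tr$true_glucose, 1) - 110), 15)
})
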