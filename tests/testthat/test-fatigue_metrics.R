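test_that("activity detection uses a strict 5 %MVC threshold", {
  expect_identical(activity_mask(c(4.9, 5.0, 5.1)), c(FALSE, FALSE, TRUE))
  expect_identical(activity_mask(rep(0, 4)), rep(FALSE, 4))
  expect_identical(activity_mask(rep(50, 4)), rep(TRUE, 4))
})

test_that("duty cycle is the active fraction of work time", {
  expect_equal(duty_cycle(rep(c(TRUE, FALSE), c(180, 420))), 0.30)
  expect_equal(duty_cycle(rep(FALSE, 10)), 0)
  expect_equal(duty_cycle(rep(TRUE, 10)), 1)
  expect_error(duty_cycle(logical(0)), "empty")
})

test_that("mean active amplitude averages active intervals only", {
  v <- c(3, 6, 10, 4)
  m <- activity_mask(v, 5)
  expect_equal(mean_active_amplitude(v, m), 8)
  expect_true(is.na(mean_active_amplitude(c(1, 2), c(FALSE, FALSE))))
  expect_equal(mean_active_amplitude(rep(30, 5), rep(TRUE, 5)), 30)
})

test_that("TLV curve hits the calibration anchor and decreases in duty cycle", {
  curve <- tlv_curve()
  expect_identical(tlv(0.5, curve), 20)
  expect_gt(tlv(0.1, curve), tlv(0.5, curve))
  expect_identical(tlv(0, curve), curve$cap)
  # below the floor, evaluated at the floor
  expect_equal(tlv(0.001, curve), tlv(curve$dc_floor, curve))
  expect_error(tlv(1.2, curve), "within")
  expect_error(tlv(-0.1, curve), "within")

  dc <- seq(curve$dc_floor, 1, by = 0.001)
  v <- tlv(dc, curve)
  expect_true(all(diff(v) < 0))
  expect_true(all(v > 0 & v <= curve$cap))
})

test_that("fatigue risk value is amplitude minus TLV, exactly", {
  expect_equal(fatigue_risk(25, 20), 5)
  expect_equal(fatigue_risk(20, 20), 0)
  expect_equal(fatigue_risk(15, 20), -5)
  set.seed(7)
  maa <- runif(50, 0, 60)
  tl <- runif(50, 5, 100)
  expect_identical(fatigue_risk(maa, tl) + tl, maa)
})

test_that("muscle_fatigue_metrics ties its fields together", {
  s <- make_series(c(2, 8, 30, 40, 3, 1))
  m <- muscle_fatigue_metrics(s)
  expect_equal(m$duty_cycle, m$n_active / m$n_total)
  expect_equal(m$fatigue_risk_value,
               m$mean_active_amplitude - m$tlv)
  expect_equal(m$mean_active_amplitude, mean(c(8, 30, 40)))
  # inactive muscle: TLV capped, FRV undefined
  quiet <- muscle_fatigue_metrics(make_series(rep(1, 6)))
  expect_equal(quiet$tlv, tlv_curve()$cap)
  expect_true(is.na(quiet$fatigue_risk_value))
  expect_true(is.na(quiet$mean_active_amplitude))
})

test_that("bilateral max rule retains the higher side and keeps the FRV identity", {
  left <- make_series(c(10, 20, 3, 3, 10, 20), side = "left")
  right <- make_series(c(15, 30, 4, 4, 15, 30), side = "right")
  ml <- muscle_fatigue_metrics(left)
  mr <- muscle_fatigue_metrics(right)
  red <- bilateral_reduce(left, right, "anterior_deltoid")
  # right dominates both amplitude and duty cycle, so the reduction equals it
  expect_equal(red$mean_active_amplitude, mr$mean_active_amplitude)
  expect_equal(red$fatigue_risk_value, mr$fatigue_risk_value)
  expect_equal(red$fatigue_risk_value,
               red$mean_active_amplitude - red$tlv)

  # identical sides: result equals either side
  same <- bilateral_reduce(left, left, "biceps_brachii")
  expect_equal(same$fatigue_risk_value, ml$fatigue_risk_value)
  expect_equal(same$mean_active_amplitude, ml$mean_active_amplitude)

  # never below either side, per metric, across random series
  set.seed(8)
  for (i in 1:20) {
    a <- make_series(runif(12, 0, 50))
    b <- make_series(runif(12, 0, 50))
    ma <- muscle_fatigue_metrics(a)
    mb <- muscle_fatigue_metrics(b)
    r <- bilateral_reduce(a, b, "upper_trapezius")
    expect_gte(r$duty_cycle, max(ma$duty_cycle, mb$duty_cycle))
    expect_gte(r$mean_active_amplitude,
               max(ma$mean_active_amplitude, mb$mean_active_amplitude))
    expect_gte(r$fatigue_risk_value,
               max(ma$fatigue_risk_value, mb$fatigue_risk_value))
  }
})

test_that("erector spinae sides are averaged before metrics", {
  left <- make_series(c(10, 2), muscle = "lumbar_erector_spinae")
  right <- make_series(c(2, 10), muscle = "lumbar_erector_spinae",
                       side = "right")
  red <- bilateral_reduce(left, right, "lumbar_erector_spinae")
  # averaged series is [6, 6]: fully active, unlike either side alone
  expect_equal(red$duty_cycle, 1)
  expect_equal(muscle_fatigue_metrics(left)$duty_cycle, 0.5)
  expect_equal(red$mean_active_amplitude, 6)
  expect_equal(red$side, "bilateral_mean")
})

test_that("benefit categories follow the meaningful-change rules", {
  expect_identical(categorize(5.0, 2.5), 1L)
  expect_identical(categorize(3.0, -2.0), 2L)
  expect_identical(categorize(-1.0, -4.0), 3L)
  expect_identical(categorize(4.0, 3.0), 4L)
  # FRV exactly 0 with the exoskeleton counts as at-or-below the TLV
  expect_identical(categorize(3.0, 0.0), 2L)
  expect_identical(categorize(0.0, -2.5), 3L)
  expect_true(is.na(categorize(NA_real_, 1)))
})

test_that("collapsing across team members averages within process", {
  df <- data.frame(process = c(1, 1, 2), value = c(10, 14, 7))
  out <- collapse_by_process(df, "value")
  expect_equal(out$value, c(12, 7))
  # 16 processes in, 16 rows out
  df16 <- data.frame(process = rep(1:16, each = 2),
                     value = rnorm(32))
  expect_equal(nrow(collapse_by_process(df16, "value")), 16L)
})

test_that("posture percentages and group means follow the TEBA sheet", {
  pb <- data.frame(process_id = 1:2, cycle_time_s = c(100, 100),
                   sec_ge60 = c(20, 40), sec_ge90 = c(15, 30),
                   sec_ge135 = c(5, 10), sec_ge180 = c(0, 0))
  pct <- posture_percentages(pb)
  expect_equal(pct$pct_ge90, c(15, 30))
  gm <- group_posture_means(pct, list(`1` = "g", `2` = "g"))
  expect_equal(gm$pct_ge60, 30)

  bad <- pb
  bad$sec_ge135 <- c(25, 50)  # exceeds sec_ge90
  expect_error(posture_percentages(bad), "non-increasing")

  teba <- read.csv(system.file("extdata", "synthetic_teba.csv",
                               package = "exofatigue"))
  pct <- posture_percentages(teba)
  expect_true(all(pct$pct_ge60 >= pct$pct_ge90))
  expect_true(all(pct$pct_ge60 <= 100))
})
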