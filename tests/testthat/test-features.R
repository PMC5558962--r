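# trapezoidal action potential with known landmarks: linear 10 ms rise to
# 1, 200 ms plateau, linear 10 ms fall, from/to baseline 0
trapezoid_ap <- function(dt = 0.1, pre = 5) {
  tt <- seq(0, 300, by = dt)
  u <- ifelse(tt < pre, 0,
       ifelse(tt < pre + 10, (tt - pre) / 10,
       ifelse(tt < pre + 210, 1,
       ifelse(tt < pre + 220, 1 - (tt - pre - 210) / 10, 0))))
  data.frame(time = tt, u = u)
}

test_that("AP features of a constructed trapezoid are recovered exactly", {
  tr <- trapezoid_ap()
  ft <- extract_ap_features(tr$time, tr$u)
  # 10% crossing on the rise at pre+1 ms, 10% level on the fall at
  # pre+219 ms -> APD90 = 218 ms; rise 10->90% = 8 ms; slope 0.1/ms
  expect_equal(ft$apd90, 218, tolerance = 0.01)
  expect_equal(ft$ap_rise, 8, tolerance = 0.01)
  expect_equal(ft$vmax, 0.1, tolerance = 1e-6)
  expect_true(is.na(ft$notch_magnitude))
})

test_that("interval features are invariant to time shift and amplitude scale", {
  tr <- trapezoid_ap()
  a <- extract_ap_features(tr$time, tr$u)
  b <- extract_ap_features(tr$time + 137, tr$u * 85.7 - 84)
  expect_equal(a$apd90, b$apd90, tolerance = 1e-9)
  expect_equal(a$ap_rise, b$ap_rise, tolerance = 1e-9)
})

test_that("notch features: index is the exact product, cooling deepens the epi notch", {
  tr37 <- simulate_cell("EPI", 37, n_beats = 1, cl = 600, dt = 0.02,
                        record_dt = 0.1)
  tr29 <- simulate_cell("EPI", 29, n_beats = 1, cl = 600, dt = 0.02,
                        record_dt = 0.1)
  f37 <- extract_ap_features(tr37$time, tr37$u)
  f29 <- extract_ap_features(tr29$time, tr29$u)
  expect_equal(f37$notch_index, f37$notch_magnitude * f37$notch_duration)
  expect_gt(f29$notch_magnitude, f37$notch_magnitude)
  expect_gt(f29$notch_duration, f37$notch_duration)
  expect_gt(f29$notch_index, f37$notch_index)
})

test_that("no-beat traces raise an explicit error", {
  tt <- seq(0, 100, 0.1)
  expect_error(extract_ap_features(tt, rep(0.001, length(tt))), "no action")
})

test_that("dispersion of repolarisation is max minus min and permutation-invariant", {
  expect_equal(dor(c(250, 250, 250)), 0)
  x <- c(260, 310, 285, 270)
  expect_equal(dor(x), 50)
  expect_equal(dor(sample(x)), 50)
  expect_error(dor(300), "at least two")
})

test_that("ECG landmarks planted in a synthetic beat are recovered", {
  tt <- seq(0, 600, by = 1)
  gauss <- function(t0, sd, amp) amp * exp(-((tt - t0) / sd)^2 / 2)
  # Q down at 20, R up at 40, S down at 60, J hump at 85, T wave at 400
  amp <- gauss(40, 5, 1) - gauss(20, 3, 0.25) - gauss(60, 4, 0.35) +
    gauss(85, 8, 0.18) + gauss(400, 35, 0.5)
  ft <- extract_ecg_features(tt, amp, qrs_window = 75, j_window = 100)
  expect_equal(ft$t_q, 20, tolerance = 1)
  expect_equal(ft$t_s, 60, tolerance = 1)
  expect_equal(ft$qrs, 40, tolerance = 2)
  expect_equal(ft$t_j, 85, tolerance = 2)
  expect_equal(ft$j_amplitude, 0.18, tolerance = 0.02)
  expect_equal(ft$t_tpeak, 400, tolerance = 1)
  # T end: 90% recurrence of the 0.5 excursion at t0 + sd*sqrt(2 ln 10)
  expect_equal(ft$t_tend, 400 + 35 * sqrt(2 * log(10)), tolerance = 2)
  expect_equal(ft$tpte, ft$t_tend - ft$t_tpeak)
  expect_equal(ft$qt, ft$t_tend - ft$t_q_onset)
})

test_that("wavefront-gradient CV recovers a planar wave and guards infinite speed", {
  g <- build_wedge(lx = 1, ly = 0, lz = 0.5, ds = 0.05)
  # planar wave along x at 50 cm/s: t = x / 0.05 cm/ms
  act <- rep(g$x / 0.05, times = g$dims[3])
  cv <- cv_from_activation_map(act, g)
  inner <- cv[2:(g$dims[1] - 1), 1, ]
  expect_lt(max(abs(inner - 50) / 50), 0.02)
  expect_true(all(is.na(cv_from_activation_map(rep(3, prod(g$dims)), g))))
})

test_that("strand gradient CV agrees with the two-point measure", {
  rec <- run_strand(coarse_strand("ENDO", D = 0.124))
  cv2 <- measure_cv(rec)
  g1 <- list(dims = c(length(rec$x), 1L, 1L), ds = rec$spec$ds)
  cvg <- cv_from_activation_map(rec$act, g1)
  mid <- seq(round(0.3 * length(rec$x)), round(0.7 * length(rec$x)))
  expect_lt(abs(median(cvg[mid], na.rm = TRUE) - cv2) / cv2, 0.02)
})
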