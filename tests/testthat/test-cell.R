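test_that("rest is an equilibrium of the cell model", {
  p <- build_cell_parameters("EPI", 37)
  st <- mv_initial_state()
  J <- mv_currents(st, p)
  expect_equal(J$J_fi, 0)
  expect_equal(J$J_so, 0)
  expect_equal(J$J_si, 0)
  # u, v, w stay put; s relaxes toward its resting activation s_inf(0)
  st2 <- st
  for (i in 1:100) st2 <- mv_step(st2, p, i_stim = 0, dt = 0.1)
  expect_equal(st2$u, 0)
  expect_equal(st2$v, 1)
  expect_equal(st2$w, 1)
  s_inf0 <- (1 + tanh(p[["k_s"]] * (0 - p[["u_s"]]))) / 2
  expect_lt(abs(st2$s - s_inf0), s_inf0) # monotone approach, no blow-up
  # from the exact fixed point nothing moves
  st3 <- mv_step(list(u = 0, v = 1, w = 1, s = s_inf0), p, 0, 0.05)
  expect_equal(st3$u, 0)
  expect_equal(st3$s, s_inf0, tolerance = 1e-12)
})

test_that("slow inward current is inward above the w-threshold", {
  p <- build_cell_parameters("ENDO", 37)
  J <- mv_currents(list(u = 0.5, v = 0.5, w = 0.8, s = 0.6), p)
  expect_lt(J$J_si, 0)
  expect_gt(J$J_so, 0)
})

test_that("R stepper, compiled solver and independent oracle agree on a paced beat", {
  p <- build_cell_parameters("EPI", 37)
  dt <- 0.05
  dur <- 400
  orc <- oracle_cell_trace(p, dur, dt, stim_amp = 1.2, stim_dur = 1)
  # package R stepper
  st <- mv_initial_state()
  uR <- numeric(nrow(orc))
  uR[1] <- st$u
  for (i in seq_len(nrow(orc) - 1)) {
    t <- (i - 1) * dt
    st <- mv_step(st, p, i_stim = if (t < 1 - 1e-9) 1.2 else 0, dt = dt)
    uR[i + 1] <- st$u
  }
  expect_lt(max(abs(uR - orc$u)), 1e-12)
  # compiled zero-diffusion path
  tr <- simulate_cell("EPI", 37, n_beats = 1, cl = dur, dt = dt,
                      stim_amp = 1.2, stim_dur = 1)
  expect_lt(max(abs(tr$u - orc$u)), 1e-12)
})

test_that("halving the time step changes single-cell APD90 by < 0.5 ms", {
  apd <- vapply(c(0.02, 0.01), function(dt) {
    tr <- simulate_cell("EPI", 37, n_beats = 1, cl = 500, dt = dt)
    extract_ap_features(tr$time, tr$u)$apd90
  }, numeric(1))
  expect_lt(abs(diff(apd)), 0.5)
})

test_that("instability and gate-overshoot guards name the offending dt", {
  p <- build_cell_parameters("EPI", 37)
  expect_error(mv_step(mv_initial_state(), p, 0, -1), "dt")
  st <- list(u = 0.5, v = 0.5, w = 0.5, s = 0.5)
  expect_error(mv_step(st, p, i_stim = NaN, dt = 0.1), "instability")
})

test_that("cooling leaves AP amplitude nearly unchanged but slows the upstroke", {
  temps <- seq(37, 27, -2)
  feats <- lapply(temps, function(temp) {
    tr <- simulate_cell("EPI", temp, n_beats = 2, cl = 1000, dt = 0.02,
                        record_dt = 0.1)
    b <- tr[tr$time >= 1000, ]
    ft <- extract_ap_features(b$time - 1000, b$u)
    list(amp = max(b$u) - b$u[1], vmax = ft$vmax, rise = ft$ap_rise,
         apd = ft$apd90)
  })
  amp <- vapply(feats, `[[`, numeric(1), "amp")
  expect_lt(max(abs(amp - amp[1]) / amp[1]), 0.025)
  # Vmax decreases, rise time and APD90 increase monotonically on cooling
  expect_true(all(diff(vapply(feats, `[[`, numeric(1), "vmax")) < 0))
  expect_true(all(diff(vapply(feats, `[[`, numeric(1), "rise")) > 0))
  expect_true(all(diff(vapply(feats, `[[`, numeric(1), "apd")) > 0))
})

test_that("equilibria are temperature-invariant", {
  for (temp in c(27, 32, 37)) {
    p <- build_cell_parameters("M", temp)
    st <- mv_step(list(u = 0, v = 1, w = 1, s = 0), p, 0, 0.01)
    expect_equal(st$u, 0)
    expect_equal(st$v, 1)
    expect_equal(st$w, 1)
  }
})
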