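test_that("Q10 scaling law: identity at reference, correct direction and value", {
  expect_equal(temperature_scale(100, 0.69, 37), 100)
  expect_equal(temperature_scale(100, 0.69, 27), 100 / 0.69,
               tolerance = 1e-12)
  expect_equal(temperature_scale(0.692, 1.35, 27), 0.692 / 1.35,
               tolerance = 1e-12)
  # q10 < 1 grows on cooling, q10 > 1 shrinks
  expect_gt(temperature_scale(1, 0.5, 30), 1)
  expect_lt(temperature_scale(1, 2.0, 30), 1)
  expect_error(temperature_scale(-1, 0.69, 30), "positive")
  expect_error(temperature_scale(1, 0, 30), "positive")
  expect_error(temperature_scale(1, 0.5, 10), "temperature")
})

test_that("default coefficient tables carry the calibrated values", {
  q <- q10_defaults()
  expect_equal(q$q10_apd, c(0.69, 0.53, 0.58))
  expect_equal(q$q10_vmax, c(0.57, 0.67, 0.60))
  expect_equal(q$q10_notch, c(0.24, 0.53, 0.58))
  expect_equal(q$q10_D, c(1.35, 1.39, 1.40))
  expect_equal(attr(q, "q10_cl"), 0.28)
  expect_equal(unname(capd_defaults()), c(1.05, 1.0, 1.40))
  # base parameter sets: three cell types, all time constants positive
  for (ct in c("EPI", "M", "ENDO")) {
    p <- mv_parameters(ct)
    taus <- p[grep("^tau_", names(p))]
    expect_true(all(taus > 0))
  }
  expect_error(mv_parameters("purkinje"), "unknown cell type")
})

test_that("cAPD correction scales exactly the repolarisation constants", {
  for (ct in c("EPI", "M", "ENDO")) {
    base <- mv_parameters(ct)
    corr <- apply_capd(base)
    f <- capd_defaults()[[ct]]
    scaled <- c("tau_wplus", "tau_si", "tau_so1", "tau_so2")
    expect_equal(unclass(corr[scaled]), unclass(base[scaled]) * f)
    rest <- setdiff(names(base), scaled)
    expect_identical(unclass(corr[rest]), unclass(base[rest]))
  }
  # M factor is 1: parameters unchanged
  expect_identical(unclass(apply_capd(mv_parameters("M"))),
                   unclass(mv_parameters("M")))
})

test_that("temperature-scaled parameter build composes cAPD and Q10 groups", {
  p37 <- build_cell_parameters("EPI", 37)
  expect_equal(unclass(p37), unclass(apply_capd(mv_parameters("EPI"))))
  p27 <- build_cell_parameters("EPI", 27)
  base <- mv_parameters("EPI")
  # cAPD does not touch tau_fi; vmax group scaled by 0.57^-1
  expect_equal(p27[["tau_fi"]], base[["tau_fi"]] / 0.57, tolerance = 1e-12)
  expect_equal(p27[["tau_vplus"]], base[["tau_vplus"]] / 0.57,
               tolerance = 1e-12)
  # APD group carries both cAPD and Q10
  expect_equal(p27[["tau_si"]], base[["tau_si"]] * 1.05 / 0.69,
               tolerance = 1e-12)
  # notch group
  expect_equal(p27[["tau_s1"]], base[["tau_s1"]] / 0.24, tolerance = 1e-12)
  # untouched constants
  expect_equal(p27[["tau_v1minus"]], base[["tau_v1minus"]])
  # M at 32 degC
  m32 <- build_cell_parameters("M", 32)
  expect_equal(m32[["tau_si"]], mv_parameters("M")[["tau_si"]] * 0.53^-0.5,
               tolerance = 1e-12)
})

test_that("cycle-length adaptation follows the 0.28 Q10 law", {
  expect_equal(adapt_cycle_length(37), 1000)
  expect_equal(adapt_cycle_length(27), 1000 / 0.28, tolerance = 1e-9)
  expect_equal(adapt_cycle_length(32), 1000 * 0.28^-0.5, tolerance = 1e-9)
  # monotone increasing as T falls
  cls <- adapt_cycle_length(seq(37, 27, -2))
  expect_true(all(diff(cls) > 0))
})

test_that("u <-> mV map is affine, monotone and invertible", {
  expect_equal(map_u_to_mV(0), -84)
  u <- seq(-0.1, 1.6, length.out = 50)
  v <- map_u_to_mV(u)
  expect_true(all(diff(v) > 0))
  expect_equal(map_mV_to_u(v), u, tolerance = 1e-12)
})
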