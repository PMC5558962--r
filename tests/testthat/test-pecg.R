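test_that("uniform membrane fields produce zero lead-field potential", {
  g <- build_wedge(lx = 0.4, ly = 0.4, lz = 0.4, ds = 0.1)
  tens <- diffusion_tensors(g, 37)
  el <- electrode_setup(g, 1)
  expect_equal(unipolar_potential(rep(0.7, prod(g$dims)), tens, g, el$epi), 0)
})

test_that("electrodes must lie outside the tissue", {
  g <- build_wedge(lx = 0.4, ly = 0.4, lz = 0.4, ds = 0.1)
  tens <- diffusion_tensors(g, 37)
  expect_error(unipolar_potential(numeric(prod(g$dims)), tens, g,
                                  c(0.2, 0.2, 0.2)), "inside")
  expect_error(electrode_setup(g, -1), "outside")
})

test_that("compact source matches the closed-form point dipole far away", {
  # isotropic medium, smooth step along x: at 10x the block size the
  # lead-field sum must approach the point-dipole potential -p/r^2 with
  # p the (discrete) dipole strength 85.7 * sum(D du/dx) dV
  g <- build_wedge(lx = 1, ly = 1, lz = 1, ds = 0.1,
                   layers = c(EPI = 0.1, M = 0.3, ENDO = 0.6))
  N <- prod(g$dims)
  tens <- cbind(xx = rep(1, N), yy = 1, zz = 1, xy = 0, xz = 0, yz = 0)
  coords <- expand.grid(x = g$x, y = g$y, z = g$z)
  u <- (1 + tanh((coords$x - 0.5) / 0.15)) / 2
  el <- c(10.5, 0.5, 0.5)   # on the x axis through the step centre
  phi <- unipolar_potential(u, tens, g, el)
  ua <- array(u, dim = g$dims)
  nx <- g$dims[1]
  ddx <- array(0, g$dims)
  ddx[2:(nx - 1), , ] <- (ua[3:nx, , ] - ua[1:(nx - 2), , ]) / (2 * g$ds)
  ddx[1, , ] <- (ua[2, , ] - ua[1, , ]) / g$ds
  ddx[nx, , ] <- (ua[nx, , ] - ua[nx - 1, , ]) / g$ds
  p_dip <- 85.7 * sum(ddx) * g$ds^3
  r <- 10          # electrode to step centre
  phi_exact <- -p_dip / r^2
  expect_lt(abs(phi - phi_exact) / abs(phi_exact), 0.05)
})

test_that("pseudo-ECG is linear in the membrane excursion", {
  g <- build_wedge(lx = 0.5, ly = 0, lz = 0.5, ds = 0.05)
  N <- prod(g$dims)
  tens <- diffusion_tensors(g, 37)
  el <- electrode_setup(g, 1)
  set.seed(1)
  u <- runif(N)
  a <- unipolar_potential(u, tens, g, el$epi)
  b <- unipolar_potential(3 * u, tens, g, el$epi)
  expect_equal(b, 3 * a, tolerance = 1e-9)
})

test_that("quiescent tissue yields a flat zero pECG trace", {
  g <- build_wedge(lx = 0.5, ly = 0, lz = 0.5, ds = 0.05)
  N <- prod(g$dims)
  tens <- diffusion_tensors(g, 37)
  el <- electrode_setup(g, 1)
  ecg <- list(h_epi = cryoEP:::.lead_field_weights(g, tens, el$epi),
              h_endo = cryoEP:::.lead_field_weights(g, tens, el$endo),
              stride = 20L)
  run <- cryoEP:::.mono_run_raw(g$dims, g$ds, tens / 1000,
                                rep(0L, N), cryoEP:::.param_matrix(
                                  list(build_cell_parameters("EPI"))),
                                cryoEP:::.flat_state(N), integer(0), 0, 0,
                                numeric(0), duration = 50, dt = 0.05,
                                ecg = ecg)
  expect_true(all(abs(run$ecg) < 1e-12))
})
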