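test_that("wedge geometry honours extents, layering and fiber rotation", {
  g <- build_wedge()                      # 2 x 2 x 1 cm at 0.2 mm
  expect_equal(g$dims, c(101L, 101L, 51L))
  # layers from the epicardial face: 1 mm EPI, 3 mm M, 6 mm ENDO
  ctz <- as.character(g$cell_type[1 + (seq_len(51) - 1) * 101 * 101])
  expect_true(all(ctz[g$z < 0.1] == "EPI"))
  expect_true(all(ctz[g$z >= 0.1 & g$z < 0.4] == "M"))
  expect_true(all(ctz[g$z >= 0.4] == "ENDO"))
  # helical fibers: -60 at the epicardial face, 0 mid-wall, +60 endocardial
  thz <- g$theta[1 + (seq_len(51) - 1) * 101 * 101]
  expect_equal(thz[1], -60)
  expect_equal(thz[26], 0)
  expect_equal(thz[51], 60)
  expect_error(build_wedge(layers = c(EPI = 0.2, M = 0.3, ENDO = 0.6)),
               "sum to 1")
})

test_that("diffusion tensors carry the directional values and rotate about z", {
  # rotation-free field: an M node's tensor is diag(0.764, 0.236, 0.124)
  g0 <- build_wedge(ds = 0.1, theta_range = c(0, 0))
  t0 <- diffusion_tensors(g0, 37)
  nM <- which(g0$cell_type == "M")[1]
  expect_equal(unname(t0[nM, c("xx", "yy", "zz")]), c(0.764, 0.236, 0.124))
  expect_equal(unname(t0[nM, c("xy", "xz", "yz")]), c(0, 0, 0))

  g <- build_wedge(ds = 0.1)
  tens <- diffusion_tensors(g, 37)
  # an M node on the helical field: in-plane rotation, transmural pinned
  n <- which(g$cell_type == "M" & abs(g$theta + 36) < 1e-9)[1]
  DL <- 0.764; DT <- 0.236
  c2 <- cos(g$theta[n] * pi / 180)^2
  expect_equal(unname(tens[n, "zz"]), 0.124)
  expect_equal(unname(tens[n, "xx"]), DL * c2 + DT * (1 - c2),
               tolerance = 1e-12)
  # full tensors are symmetric positive definite with the directional
  # eigenvalues
  for (n in c(1L, 500L, nrow(tens))) {
    Dm <- matrix(c(tens[n, "xx"], tens[n, "xy"], tens[n, "xz"],
                   tens[n, "xy"], tens[n, "yy"], tens[n, "yz"],
                   tens[n, "xz"], tens[n, "yz"], tens[n, "zz"]), 3, 3)
    ev <- sort(eigen(Dm, symmetric = TRUE, only.values = TRUE)$values)
    ct <- as.character(g$cell_type[n])
    d <- diffusion_defaults()
    dd <- sort(unlist(d[d$cell_type == ct,
                        c("D_long", "D_trans", "D_transmural")]))
    expect_equal(ev, unname(dd), tolerance = 1e-12)
  }
})

test_that("diffusion temperature scaling obeys the Q10 law and the gap switch", {
  expect_equal(scale_diffusion(0.9, 1.40, 37), 0.9)
  expect_equal(scale_diffusion(0.9, 1.40, 27), 0.9 / 1.40, tolerance = 1e-12)
  expect_equal(scale_diffusion(0.9, 1.40, 27, gap_q10 = FALSE), 0.9)
  expect_error(scale_diffusion(-0.1, 1.4, 30), "positive")
})

test_that("divergence operator: constant fields, Laplacian reduction", {
  g <- build_wedge(lx = 0.6, ly = 0.6, lz = 0.6, ds = 0.1)
  N <- prod(g$dims)
  tens <- diffusion_tensors(g, 37)
  expect_equal(anisotropic_divergence(rep(2.5, N), tens, g), rep(0, N))
  # homogeneous isotropic tensor equals the 7-point Laplacian
  iso <- cbind(xx = rep(1, N), yy = 1, zz = 1, xy = 0, xz = 0, yz = 0)
  set.seed(42)
  f <- array(rnorm(N), dim = g$dims)
  lap7 <- array(0, dim = g$dims)
  pad <- function(a, ax, k) {
    # reflected (Neumann) neighbour shift
    idx <- lapply(dim(a), seq_len)
    idx[[ax]] <- pmin(pmax(idx[[ax]] + k, 1L), dim(a)[ax])
    do.call(`[`, c(list(a), idx))
  }
  for (ax in 1:3) {
    lap7 <- lap7 + (pad(f, ax, 1L) - 2 * f + pad(f, ax, -1L)) / g$ds^2
  }
  got <- array(anisotropic_divergence(f, iso, g), dim = g$dims)
  expect_lt(max(abs(got - lap7)), 1e-11)
})

test_that("no-flux diffusion conserves the discrete integral with reaction off", {
  g <- build_wedge(lx = 1, ly = 0, lz = 0.5, ds = 0.05)
  N <- prod(g$dims)
  tens <- diffusion_tensors(g, 31) / 1000
  set.seed(7)
  state <- list(u = runif(N), v = rep(1, N), w = rep(1, N), s = numeric(N))
  run <- cryoEP:::.mono_run_raw(g$dims, g$ds, tens,
                                rep(0L, N), cryoEP:::.param_matrix(
                                  list(mv_parameters("EPI"))),
                                state, integer(0), 0, 0, numeric(0),
                                duration = 100 * 0.05, dt = 0.05,
                                reaction_on = FALSE)
  expect_lt(abs(sum(run$u) - sum(state$u)) / abs(sum(state$u)), 1e-8)
})

test_that("zero-diffusion tissue reproduces independent single-cell traces", {
  nx <- 4L
  params <- cryoEP:::.param_matrix(lapply(c("EPI", "M", "ENDO", "EPI"),
                                          build_cell_parameters,
                                          temperature = 31))
  tens <- matrix(0, nx, 6)
  run <- cryoEP:::.mono_run_raw(c(nx, 1L, 1L), 0.02, tens, 0:3, params,
                                cryoEP:::.flat_state(nx),
                                stim_nodes = 0:3, stim_amp = 1.2,
                                stim_dur = 1, stim_times = 0,
                                duration = 300, dt = 0.05,
                                trace_nodes = 0:3, trace_stride = 1L)
  for (m in 1:3) {
    orc <- oracle_cell_trace(build_cell_parameters(c("EPI", "M", "ENDO")[m],
                                                   31),
                             300, 0.05, stim_amp = 1.2, stim_dur = 1)
    expect_lt(max(abs(run$traces[, m] - orc$u)), 1e-12)
  }
})
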