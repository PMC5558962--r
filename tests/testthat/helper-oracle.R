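# Independent line-by-line transcription of the four-variable minimal
# ventricular model equations, written directly from the published system
# (Heaviside-gated currents, tanh-blended time constants) in a vectorised
# style unrelated to the package's stepper. Used as the oracle for
# single-cell trajectories.
oracle_mv_derivs <- function(u, v, w, s, p, i_stim = 0) {
  H <- function(x) ifelse(x >= 0, 1, 0)
  tv  <- ifelse(u >= p[["theta_vminus"]], p[["tau_v2minus"]], p[["tau_v1minus"]])
  tw  <- p[["tau_w1minus"]] + (p[["tau_w2minus"]] - p[["tau_w1minus"]]) *
    (1 + tanh(p[["k_wminus"]] * (u - p[["u_wminus"]]))) / 2
  tso <- p[["tau_so1"]] + (p[["tau_so2"]] - p[["tau_so1"]]) *
    (1 + tanh(p[["k_so"]] * (u - p[["u_so"]]))) / 2
  ts  <- ifelse(u >= p[["theta_w"]], p[["tau_s2"]], p[["tau_s1"]])
  to  <- ifelse(u >= p[["theta_o"]], p[["tau_o2"]], p[["tau_o1"]])
  vinf <- ifelse(u < p[["theta_vminus"]], 1, 0)
  winf <- ifelse(u >= p[["theta_o"]], p[["w_inf_star"]],
                 1 - u / p[["tau_winf"]])
  jfi <- -v * H(u - p[["theta_v"]]) * (u - p[["theta_v"]]) *
    (p[["u_u"]] - u) / p[["tau_fi"]]
  jso <- (u - p[["u_o"]]) * (1 - H(u - p[["theta_w"]])) / to +
    H(u - p[["theta_w"]]) / tso
  jsi <- -H(u - p[["theta_w"]]) * w * s / p[["tau_si"]]
  list(
    du = -(jfi + jso + jsi) + i_stim,
    dv = ifelse(u >= p[["theta_v"]], -v / p[["tau_vplus"]], (vinf - v) / tv),
    dw = ifelse(u >= p[["theta_w"]], -w / p[["tau_wplus"]], (winf - w) / tw),
    ds = ((1 + tanh(p[["k_s"]] * (u - p[["u_s"]]))) / 2 - s) / ts,
    jfi = jfi, jso = jso, jsi = jsi
  )
}

# forward-Euler oracle trajectory of a paced single cell
oracle_cell_trace <- function(params, duration, dt, stim_amp = 1.2,
                              stim_dur = 1) {
  n <- round(duration / dt)
  u <- numeric(n + 1); v <- w <- rep(1, n + 1); s <- numeric(n + 1)
  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    d <- oracle_mv_derivs(u[i], v[i], w[i], s[i], params,
                          i_stim = if (t < stim_dur - 1e-9) stim_amp else 0)
    u[i + 1] <- u[i] + d$du * dt
    v[i + 1] <- min(max(v[i] + d$dv * dt, 0), 1)
    w[i + 1] <- min(max(w[i] + d$dw * dt, 0), 1)
    s[i + 1] <- min(max(s[i] + d$ds * dt, 0), 1)
  }
  data.frame(time = (0:n) * dt, u = u, v = v, w = w, s = s)
}

# quick coarse strand settings shared by protocol unit tests
coarse_strand <- function(ct = "ENDO", D = 0.124, temperature = 37,
                          dt = 0.05, ...) {
  strand_spec(ct, D = D, temperature = temperature, dt = dt, ...)
}
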