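#' Resting state of the minimal ventricular model
#'
#' Initial conditions (u, v, w, s) = (0, 1, 1, 0) as in the original model
#' formulation.
#'
#' @return Named list with elements `u`, `v`, `w`, `s`.
#' @export
mv_initial_state <- function() list(u = 0, v = 1, w = 1, s = 0)

## Heaviside step, H(0) = 1 (the convention is immaterial at the model's
## operating points but is fixed for bit-reproducibility across the R and
## C++ paths).
.H <- function(x) as.numeric(x >= 0)

#' The three virtual current densities of the minimal model
#'
#' Computes the fast-inward (J_fi), outward (J_so) and slow-inward (J_si)
#' current densities (1/ms, dimensionless voltage convention) for a given
#' state and (possibly temperature-scaled) parameter set. Inward currents
#' are negative.
#'
#' @param state List with `u`, `v`, `w`, `s`.
#' @param params An `mv_parameters` vector.
#' @return Named list `J_fi`, `J_so`, `J_si`.
#' @export
#' @examples
#' mv_currents(mv_initial_state(), mv_parameters("EPI"))
mv_currents <- function(state, params) {
  p <- as.list(params)
  u <- state$u
  Huv <- .H(u - p$theta_v)
  Huw <- .H(u - p$theta_w)
  Huo <- .H(u - p$theta_o)
  tau_o  <- (1 - Huo) * p$tau_o1 + Huo * p$tau_o2
  tau_so <- p$tau_so1 +
    (p$tau_so2 - p$tau_so1) * (1 + tanh(p$k_so * (u - p$u_so))) / 2
  list(
    J_fi = -state$v * Huv * (u - p$theta_v) * (p$u_u - u) / p$tau_fi,
    J_so = (u - p$u_o) * (1 - Huw) / tau_o + Huw / tau_so,
    J_si = -Huw * state$w * state$s / p$tau_si
  )
}

#' One forward-Euler step of the minimal ventricular model
#'
#' Updates the membrane variable with
#' `du = (-(J_fi + J_so + J_si) + I_stim) dt` and the three gates with the
#' model's relaxation laws. Gates are clipped to `[0, 1]` only when the
#' overshoot is below 1e-9; a larger overshoot (or any non-finite value)
#' raises a numerical-instability error naming the offending `dt`.
#'
#' @param state List with `u`, `v`, `w`, `s`.
#' @param params An `mv_parameters` vector.
#' @param i_stim Stimulus current density (1/ms), additive in `du` only.
#' @param dt Time step in ms (> 0).
#' @return Updated state list.
#' @export
mv_step <- function(state, params, i_stim = 0, dt = 0.01) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  p <- as.list(params)
  u <- state$u
  Huv  <- .H(u - p$theta_v)
  Huw  <- .H(u - p$theta_w)
  Huo  <- .H(u - p$theta_o)
  Huvm <- .H(u - p$theta_vminus)

  tau_vminus <- (1 - Huvm) * p$tau_v1minus + Huvm * p$tau_v2minus
  tau_wminus <- p$tau_w1minus +
    (p$tau_w2minus - p$tau_w1minus) *
      (1 + tanh(p$k_wminus * (u - p$u_wminus))) / 2
  tau_s <- (1 - Huw) * p$tau_s1 + Huw * p$tau_s2
  v_inf <- as.numeric(u < p$theta_vminus)
  # w_inf at max(u, 0): identical on the physical range, keeps the gate
  # target in [0, 1] under transient sub-resting u
  w_inf <- (1 - Huo) * (1 - max(u, 0) / p$tau_winf) + Huo * p$w_inf_star

  J <- mv_currents(state, params)
  u_new <- u + (-(J$J_fi + J$J_so + J$J_si) + i_stim) * dt
  v_new <- state$v +
    ((1 - Huv) * (v_inf - state$v) / tau_vminus -
       Huv * state$v / p$tau_vplus) * dt
  w_new <- state$w +
    ((1 - Huw) * (w_inf - state$w) / tau_wminus -
       Huw * state$w / p$tau_wplus) * dt
  s_new <- state$s +
    ((1 + tanh(p$k_s * (u - p$u_s))) / 2 - state$s) / tau_s * dt

  gates <- c(v_new, w_new, s_new)
  if (any(!is.finite(c(u_new, gates)))) {
    stop("numerical instability (non-finite state) at dt = ", dt,
         " ms", call. = FALSE)
  }
  over <- pmax(gates - 1, -gates, 0)
  if (any(over > 1e-9)) {
    stop("gate overshoot ", format(max(over)), " exceeds tolerance at dt = ",
         dt, " ms; reduce the time step", call. = FALSE)
  }
  gates <- pmin(pmax(gates, 0), 1)
  list(u = u_new, v = gates[1], w = gates[2], s = gates[3])
}

#' Simulate a paced single cell
#'
#' Runs an isolated (zero-diffusion) cell of the given type at the given
#' temperature, pacing with square current pulses, and returns the
#' dimensionless membrane trace. Uses the compiled solver; the pure-R
#' stepper [mv_step()] is the granular reference API.
#'
#' @param ct Cell type label.
#' @param temperature Temperature in degC.
#' @param n_beats Number of paced beats.
#' @param cl Cycle length in ms; `NULL` picks 1000 ms (fixed mode).
#' @param dt Time step in ms.
#' @param stim_amp,stim_dur Stimulus amplitude (1/ms) and duration (ms).
#' @param record_dt Sampling interval of the returned trace (ms).
#' @param coeffs,factors Q10 coefficients and cAPD factors.
#' @return A data frame with columns `time` (ms) and `u`, plus attribute
#'   `config`.
#' @export
#' @examples
#' tr <- simulate_cell("EPI", 37, n_beats = 1, cl = 500)
#' max(tr$u) > 1
simulate_cell <- function(ct, temperature = 37, n_beats = 2, cl = 1000,
                          dt = 0.01, stim_amp = 1.0, stim_dur = 1.0,
                          record_dt = dt, coeffs = q10_defaults(),
                          factors = capd_defaults()) {
  ct <- cell_type(ct)
  params <- build_cell_parameters(ct, temperature, coeffs, factors)
  run <- .mono_run_raw(
    dims = c(1L, 1L, 1L), ds = 0.02,
    tensors = matrix(0, 1, 6), ctype = 0L,
    params = .param_matrix(list(params)),
    state = .flat_state(1L),
    stim_nodes = 0L, stim_amp = stim_amp, stim_dur = stim_dur,
    stim_times = seq(0, by = cl, length.out = n_beats),
    duration = cl * n_beats, dt = dt,
    trace_nodes = 0L, trace_stride = max(1L, round(record_dt / dt)),
    act_threshold = 0.3, ecg = NULL
  )
  out <- data.frame(time = run$trace_time, u = drop(run$traces))
  attr(out, "config") <- list(cell_type = ct, temperature = temperature,
                              cl = cl, dt = dt, n_beats = n_beats)
  out
}

## Internal: parameter matrix (types x constants) for the compiled solver.
.param_matrix <- function(param_list) {
  m <- do.call(rbind, lapply(param_list, function(p) unclass(p)[.mv_param_names]))
  colnames(m) <- .mv_param_names
  m
}

## Internal: flat initial state arrays for n nodes.
.flat_state <- function(n) {
  list(u = numeric(n), v = rep(1, n), w = rep(1, n), s = numeric(n))
}
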