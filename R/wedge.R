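#' Simulate a paced ventricular wedge (3D block or 2D transmural slice)
#'
#' Builds the layered anisotropic block, paces it from a small patch at
#' the middle of the left edge of the endocardial face until the
#' steady-state criterion is met (successive-beat APD90 at a mid-wall
#' monitor node within `apd_tol`), then records an analysis beat:
#' membrane traces along the central transmural line, per-node activation
#' times, and the two unipolar electrode potentials at 1 kHz.
#'
#' The 2D transmural slice (`scale = "slice2d"`, the default) is the
#' x-z mid-plane of the block: identical layering, fiber-angle-dependent
#' in-plane diffusion and electrode geometry, at a fraction of the cost of
#' the full 3D block.
#'
#' @param temperature Temperature in degC (uniform).
#' @param cl_mode `"fixed"` (CL = 1000 ms) or `"q10"`
#'   (temperature-adapted, [adapt_cycle_length()]).
#' @param scale `"slice2d"` or `"full3d"`.
#' @param ds,dt Resolution (cm, ms).
#' @param lx,ly,lz Block extents in cm.
#' @param gap_q10 Temperature scaling of the diffusion tensors on/off
#'   (off isolates the cellular contribution to cooling effects).
#' @param apd_tol,max_beats Steady-state criterion.
#' @param stim_amp,stim_dur Stimulus amplitude (1/ms) and duration (ms).
#' @param electrode_distance Electrode-to-surface distance, cm.
#' @param coeffs,factors Q10 coefficients and cAPD factors.
#' @return List of class `"wedge_record"`: `geometry`, `temperature`,
#'   `cl`, `act` (per-node activation times of the analysis beat, ms),
#'   `line` (central transmural line: `z`, `cell_type`, trace matrix
#'   `u` of dim time x nodes, `time`), `ecg` (data frame `time`,
#'   `phi_epi`, `phi_endo` at 1 kHz), `apd_history`, `steady_beat`.
#' @export
run_wedge <- function(temperature = 37, cl_mode = c("fixed", "q10"),
                      scale = c("slice2d", "full3d"), ds = 0.02, dt = 0.02,
                      lx = 2, ly = 2, lz = 1, gap_q10 = TRUE,
                      apd_tol = 1, max_beats = 8,
                      stim_amp = .default_stim$amp,
                      stim_dur = .default_stim$dur,
                      electrode_distance = 1.0,
                      coeffs = q10_defaults(), factors = capd_defaults()) {
  cl_mode <- match.arg(cl_mode)
  scale <- match.arg(scale)
  geometry <- build_wedge(lx = lx, ly = if (scale == "slice2d") 0 else ly,
                          lz = lz, ds = ds)
  dims <- geometry$dims
  N <- prod(dims)
  tensors <- diffusion_tensors(geometry, temperature, coeffs,
                               gap_q10 = gap_q10)
  tensors_ms <- tensors / 1000
  ctype <- as.integer(geometry$cell_type) - 1L
  params <- .param_matrix(lapply(CELL_TYPES, build_cell_parameters,
                                 temperature = temperature, coeffs = coeffs,
                                 factors = factors))
  cl <- if (cl_mode == "fixed") 1000 else adapt_cycle_length(temperature)
  stim_nodes <- .stim_patch(geometry)

  # central transmural line (all z at the centre x, centre y)
  ic <- (dims[1] - 1L) %/% 2L
  jc <- (dims[2] - 1L) %/% 2L
  line_nodes <- ic + dims[1] * (jc + dims[2] * (seq_len(dims[3]) - 1L))
  k_mon <- round(0.25 * (dims[3] - 1L))       # mid-wall (M layer) monitor
  monitor <- line_nodes[k_mon + 1L]

  setup <- electrode_setup(geometry, electrode_distance)
  ecg <- list(
    h_epi = .lead_field_weights(geometry, tensors, setup$epi),
    h_endo = .lead_field_weights(geometry, tensors, setup$endo),
    stride = max(1L, round(1 / dt))           # 1 kHz
  )
  stride_fine <- max(1L, round(0.1 / dt))

  state <- .flat_state(N)
  apd_hist <- numeric(0)
  steady <- NA_integer_
  for (beat in seq_len(max_beats)) {
    run <- .mono_run_raw(dims, ds, tensors_ms, ctype, params, state,
                         stim_nodes, stim_amp, stim_dur, stim_times = 0,
                         duration = cl, dt = dt, trace_nodes = monitor,
                         trace_stride = stride_fine)
    state <- run[c("u", "v", "w", "s")]
    if (all(is.na(run$act))) {
      stop("propagation failure: no node activated within one cycle ",
           "length (beat ", beat, ")", call. = FALSE)
    }
    ft <- try(extract_ap_features(run$trace_time, drop(run$traces)),
              silent = TRUE)
    if (inherits(ft, "try-error")) {
      stop("no action potential at the monitor node (beat ", beat, ")",
           call. = FALSE)
    }
    apd_hist <- c(apd_hist, ft$apd90)
    if (beat >= 2 && abs(diff(utils::tail(apd_hist, 2))) < apd_tol) {
      steady <- beat
      break
    }
  }
  if (is.na(steady)) steady <- max_beats  # analyse the capped beat

  run <- .mono_run_raw(dims, ds, tensors_ms, ctype, params, state,
                       stim_nodes, stim_amp, stim_dur, stim_times = 0,
                       duration = cl, dt = dt, trace_nodes = line_nodes,
                       trace_stride = stride_fine, ecg = ecg)
  structure(list(
    geometry = geometry, temperature = temperature, cl = cl,
    cl_mode = cl_mode, scale = scale, gap_q10 = gap_q10,
    act = drop(run$act),
    line = list(z = geometry$z,
                cell_type = as.character(geometry$cell_type[line_nodes + 1L]),
                time = run$trace_time, u = run$traces),
    ecg = data.frame(time = run$ecg_time, phi_epi = run$ecg[, 1],
                     phi_endo = run$ecg[, 2]),
    apd_history = apd_hist, steady_beat = steady
  ), class = "wedge_record")
}

#' @export
print.wedge_record <- function(x, ...) {
  cat(sprintf(
    "Wedge record: %s, %g degC, CL %s (%.0f ms), steady at beat %d\n",
    x$scale, x$temperature, x$cl_mode, x$cl, x$steady_beat))
  invisible(x)
}

#' Configuration helper and config-driven runner
#'
#' `wedge_config()` captures the arguments of [run_wedge()];
#' `run_simulation()` executes such a configuration.
#'
#' @param ... Arguments of [run_wedge()].
#' @return `wedge_config()`: a named list of class `"wedge_config"`;
#'   `run_simulation()`: a `"wedge_record"`.
#' @export
wedge_config <- function(...) {
  cfg <- list(...)
  bad <- setdiff(names(cfg), names(formals(run_wedge)))
  if (length(bad)) {
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "wedge_config")
}

#' @rdname wedge_config
#' @param config A `"wedge_config"` object.
#' @export
run_simulation <- function(config = wedge_config()) {
  stopifnot(inherits(config, "wedge_config"))
  do.call(run_wedge, unclass(config))
}

#' Summarise a wedge analysis beat
#'
#' Extracts the quantities reported for the transmural preparation: the
#' APD90 and Vmax profiles along the central transmural line, transmural
#' dispersion of repolarisation (DOR), the epicardial notch features, the
#' bipolar pseudo-ECG features (QT, QRS, J amplitude, TpTe) and the
#' per-layer repolarisation times.
#'
#' @param record A [run_wedge()] record.
#' @return List of class `"wedge_features"`: `profile` (data frame `z`,
#'   `cell_type`, `apd90`, `vmax`, `act`, `repol`), `dor`, `notch` (epi
#'   outermost node AP features), `ecg` ([extract_ecg_features()] of the
#'   bipolar trace), `pecg` (the trace).
#' @export
wedge_features <- function(record) {
  ln <- record$line
  prof <- do.call(rbind, lapply(seq_along(ln$z), function(i) {
    ft <- try(extract_ap_features(ln$time, ln$u[, i]), silent = TRUE)
    if (inherits(ft, "try-error")) {
      return(data.frame(apd90 = NA_real_, vmax = NA_real_))
    }
    data.frame(apd90 = ft$apd90, vmax = ft$vmax)
  }))
  dims <- record$geometry$dims
  ic <- (dims[1] - 1L) %/% 2L
  jc <- (dims[2] - 1L) %/% 2L
  line_idx <- ic + dims[1] * (jc + dims[2] * (seq_len(dims[3]) - 1L)) + 1L
  act_line <- record$act[line_idx]
  profile <- data.frame(z = ln$z, cell_type = ln$cell_type,
                        apd90 = prof$apd90, vmax = prof$vmax,
                        act = act_line, repol = act_line + prof$apd90)
  epi_i <- which(ln$cell_type == "EPI")[1]
  notch <- extract_ap_features(ln$time, ln$u[, epi_i])
  trace <- bipolar_pecg(record)
  qrs_win <- max(record$act, na.rm = TRUE) + 20
  ecg_ft <- extract_ecg_features(trace$time, trace$amp,
                                 qrs_window = qrs_win)
  structure(list(profile = profile, dor = dor(profile$apd90),
                 notch = notch, ecg = ecg_ft, pecg = trace,
                 temperature = record$temperature,
                 cl_mode = record$cl_mode),
            class = "wedge_features")
}

#' @export
print.wedge_features <- function(x, ...) {
  cat(sprintf("Wedge features at %g degC (%s CL):\n", x$temperature,
              x$cl_mode))
  cat(sprintf("  DOR %.1f ms | QT %.1f ms | QRS %.1f ms | TpTe %.1f ms | J %.4g\n",
              x$dor, x$ecg$qt, x$ecg$qrs, x$ecg$tpte, x$ecg$j_amplitude))
  invisible(x)
}
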