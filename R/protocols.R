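## Default stimulus for strand and wedge pacing: 1 ms square pulse over a
## small patch (first 1 mm of a strand; a 3-node-deep patch at the middle
## of the left edge of the endocardial face in tissue). The diastolic
## threshold, determined once by bisection at the hardest condition of the
## study range (27 degC, endocardial longitudinal coupling), is ~0.32/ms
## for both patch shapes; the default amplitude 1.2/ms keeps a robust
## (~4x) capture margin across all protocols and temperatures. See the
## methods vignette.
.default_stim <- list(amp = 1.2, dur = 1.0)

#' Specification of a 1D strand protocol
#'
#' @param cell_type Cell type label.
#' @param D Scalar diffusion coefficient (cm^2/s) of the direction being
#'   modelled; `NULL` uses the cell type's longitudinal value at 37 degC,
#'   temperature-scaled by its `q10_D`.
#' @param temperature Temperature in degC.
#' @param length Strand length in cm.
#' @param ds,dt Spatial (cm) and temporal (ms) resolution.
#' @param cl Pacing cycle length in ms; `"q10"` adapts it to temperature.
#' @param gap_q10 Logical; temperature scaling of D on/off.
#' @return List of class `"strand_spec"`.
#' @export
strand_spec <- function(cell_type = "ENDO", D = NULL, temperature = 37,
                        length = 2, ds = 0.02, dt = 0.01, cl = 1000,
                        gap_q10 = TRUE) {
  ct <- cryoEP::cell_type(cell_type)
  if (identical(cl, "q10")) cl <- adapt_cycle_length(temperature)
  structure(list(cell_type = ct, D = D, temperature = temperature,
                 length = length, ds = ds, dt = dt, cl = cl,
                 gap_q10 = gap_q10),
            class = "strand_spec")
}

#' Pace a 1D strand to steady state
#'
#' Stimulates the proximal end of a homogeneous strand every cycle length
#' until the steady-state criterion is met (successive-beat APD90 at the
#' mid-strand node within `apd_tol`), then runs one analysis beat with
#' full recording: per-node activation times and a finely sampled membrane
#' trace at the mid-strand node.
#'
#' @param spec A [strand_spec()] (or a cell-type label, forwarded to it).
#' @param apd_tol Steady-state tolerance on APD90, ms.
#' @param max_beats Beat cap before declaring non-convergence.
#' @param stim_amp,stim_dur Stimulus amplitude (1/ms) and duration (ms).
#' @param coeffs,factors Q10 coefficients and cAPD factors.
#' @param ... Forwarded to [strand_spec()] when `spec` is a label.
#' @return List of class `"strand_record"`: `spec`, node coordinates `x`,
#'   activation times `act` (ms from the analysis-beat stimulus, `NA`
#'   where unactivated), mid-strand `trace` (data frame `time`, `u`,
#'   sampled every `dt`), per-beat `apd_history`, and `steady_beat`.
#' @export
#' @examples
#' \donttest{
#' rec <- run_strand(strand_spec("ENDO", D = 0.124, dt = 0.05))
#' measure_cv(rec)
#' }
run_strand <- function(spec, apd_tol = 1, max_beats = 20,
                       stim_amp = .default_stim$amp,
                       stim_dur = .default_stim$dur,
                       coeffs = q10_defaults(), factors = capd_defaults(),
                       ...) {
  if (!inherits(spec, "strand_spec")) spec <- strand_spec(spec, ...)
  nx <- round(spec$length / spec$ds) + 1L
  x <- (seq_len(nx) - 1L) * spec$ds
  D <- spec$D
  if (is.null(D)) {
    dtab <- diffusion_defaults()
    row <- dtab[dtab$cell_type == spec$cell_type, ]
    q <- coeffs$q10_D[coeffs$cell_type == spec$cell_type]
    D <- scale_diffusion(row$D_long, q, spec$temperature, spec$gap_q10)
  }
  if (D < 0) stop("D must be non-negative", call. = FALSE)
  tensors <- cbind(xx = rep(D / 1000, nx), yy = 0, zz = 0,
                   xy = 0, xz = 0, yz = 0)   # cm^2/ms
  params <- .param_matrix(list(build_cell_parameters(
    spec$cell_type, spec$temperature, coeffs, factors)))
  stim_nodes <- 0:(max(1L, round(0.1 / spec$ds)) - 1L)  # first 1 mm
  monitor <- (nx - 1L) %/% 2L                           # mid-strand node
  stride <- max(1L, round(0.1 / spec$dt))               # 0.1 ms sampling

  state <- .flat_state(nx)
  apd_hist <- numeric(0)
  steady <- NA_integer_
  for (beat in seq_len(max_beats)) {
    run <- .mono_run_raw(c(nx, 1L, 1L), spec$ds, tensors, rep(0L, nx),
                         params, state, stim_nodes, stim_amp, stim_dur,
                         stim_times = 0, duration = spec$cl, dt = spec$dt,
                         trace_nodes = monitor, trace_stride = stride)
    state <- run[c("u", "v", "w", "s")]
    if (is.na(drop(run$act)[monitor + 1L])) {
      stop("propagation failure: excitation did not reach the mid-strand ",
           "node within one cycle length (beat ", beat, ")", call. = FALSE)
    }
    ft <- try(extract_ap_features(run$trace_time, drop(run$traces)),
              silent = TRUE)
    if (inherits(ft, "try-error")) {
      stop("no complete action potential at the mid-strand node on beat ",
           beat, " (APD may exceed the cycle length)", call. = FALSE)
    }
    apd_hist <- c(apd_hist, ft$apd90)
    if (beat >= 2 && abs(diff(utils::tail(apd_hist, 2))) < apd_tol) {
      steady <- beat
      break
    }
  }
  if (is.na(steady)) {
    stop("steady state not reached in ", max_beats, " beats (last APD ",
         "change ", signif(abs(diff(utils::tail(apd_hist, 2))), 3), " ms)",
         call. = FALSE)
  }
  # analysis beat, finely sampled
  run <- .mono_run_raw(c(nx, 1L, 1L), spec$ds, tensors, rep(0L, nx),
                       params, state, stim_nodes, stim_amp, stim_dur,
                       stim_times = 0, duration = spec$cl, dt = spec$dt,
                       trace_nodes = monitor, trace_stride = 1L)
  structure(list(
    spec = spec, D = D, x = x,
    act = drop(run$act),
    trace = data.frame(time = run$trace_time, u = drop(run$traces)),
    apd_history = apd_hist, steady_beat = steady, monitor = monitor + 1L
  ), class = "strand_record")
}

#' @export
print.strand_record <- function(x, ...) {
  cat(sprintf(
    "Strand record: %s, D = %.4g cm^2/s, %g degC, steady at beat %d\n",
    x$spec$cell_type, x$D, x$spec$temperature, x$steady_beat))
  invisible(x)
}

#' Two-point conduction velocity on a strand
#'
#' `CV = (x2 - x1) / (t(x2) - t(x1))` from the activation times of the
#' analysis beat, by default between 4 mm and 16 mm from the stimulated
#' end.
#'
#' @param record A [run_strand()] record.
#' @param x1,x2 Measurement positions in cm.
#' @return CV in cm/s.
#' @export
measure_cv <- function(record, x1 = 0.4, x2 = 1.6) {
  i1 <- which.min(abs(record$x - x1))
  i2 <- which.min(abs(record$x - x2))
  t1 <- record$act[i1]
  t2 <- record$act[i2]
  if (is.na(t1) || is.na(t2)) {
    stop("measurement position not activated", call. = FALSE)
  }
  (record$x[i2] - record$x[i1]) / (t2 - t1) * 1000
}

#' Calibrate the diffusion coefficient to a target conduction velocity
#'
#' Log-space bisection on the monotone map D -> strand CV until the
#' measured CV is within `rel_tol` of the target.
#'
#' @param cell_type Cell type label.
#' @param target_cv Target CV in cm/s (> 0).
#' @param temperature Temperature in degC.
#' @param bracket Search interval for D, cm^2/s.
#' @param rel_tol Relative CV tolerance.
#' @param ... Forwarded to [strand_spec()] (e.g. `ds`, `dt`).
#' @return The calibrated D in cm^2/s, with attribute `cv` (the achieved
#'   CV) and `iterations`.
#' @export
calibrate_diffusion <- function(cell_type, target_cv, temperature = 37,
                                bracket = c(1e-3, 2), rel_tol = 0.005,
                                ...) {
  if (!is.finite(target_cv) || target_cv <= 0) {
    stop("target CV must be positive", call. = FALSE)
  }
  cv_of <- function(D) {
    rec <- try(run_strand(strand_spec(cell_type, D = D,
                                      temperature = temperature, ...)),
               silent = TRUE)
    if (inherits(rec, "try-error")) return(0)   # conduction block
    measure_cv(rec)
  }
  lo <- log(bracket[1]); hi <- log(bracket[2])
  cv_lo <- cv_of(exp(lo)); cv_hi <- cv_of(exp(hi))
  if (target_cv < cv_lo || target_cv > cv_hi) {
    stop(sprintf(
      "calibration failure: target %.3g cm/s outside achievable range [%.3g, %.3g] for bracket [%g, %g] cm^2/s",
      target_cv, cv_lo, cv_hi, bracket[1], bracket[2]), call. = FALSE)
  }
  it <- 0L
  repeat {
    it <- it + 1L
    mid <- (lo + hi) / 2
    cv <- cv_of(exp(mid))
    if (abs(cv - target_cv) / target_cv < rel_tol || it >= 60L) break
    if (cv < target_cv) lo <- mid else hi <- mid
  }
  if (abs(cv - target_cv) / target_cv >= rel_tol) {
    stop("calibration failure: did not converge (last CV ", signif(cv, 4),
         " cm/s)", call. = FALSE)
  }
  structure(exp(mid), cv = cv, iterations = it)
}

#' Strand feature sweep across temperatures
#'
#' Runs the Q10 strand protocol (2 cm strand, dt = 0.1 ms, ds = 0.2 mm,
#' CL = 1000 ms by default) at each temperature with the full temperature
#' model (time-constant scaling and, optionally, diffusion scaling) and
#' extracts APD90, Vmax, AP_rise and the two-point CV.
#'
#' @param cell_type Cell type label.
#' @param temperatures Temperatures in degC; must include 37.
#' @param dt,ds,cl Strand resolution and pacing cycle length (`"q10"` for
#'   temperature-adapted pacing).
#' @param gap_q10 Temperature scaling of D on/off.
#' @param coeffs Q10 coefficient table.
#' @param ... Forwarded to [run_strand()].
#' @return Data frame with one row per temperature and columns
#'   `temperature`, `apd90`, `vmax`, `ap_rise`, `cv`.
#' @export
q10_strand_sweep <- function(cell_type, temperatures = seq(37, 27, by = -2),
                             dt = 0.1, ds = 0.02, cl = 1000, gap_q10 = TRUE,
                             coeffs = q10_defaults(), ...) {
  rows <- lapply(temperatures, function(temp) {
    sp <- strand_spec(cell_type, temperature = temp, dt = dt, ds = ds,
                      cl = cl, gap_q10 = gap_q10)
    rec <- run_strand(sp, coeffs = coeffs, ...)
    ft <- extract_ap_features(rec$trace$time, rec$trace$u)
    data.frame(temperature = temp, apd90 = ft$apd90, vmax = ft$vmax,
               ap_rise = ft$ap_rise, cv = measure_cv(rec))
  })
  do.call(rbind, rows)
}

#' Fitted Q10 of a swept strand feature
#'
#' Normalises the feature column of a [q10_strand_sweep()] to its value at
#' 37 degC and fits the Q10 relative-change law.
#'
#' @param sweep Data frame from [q10_strand_sweep()].
#' @param feature Column name (`"apd90"`, `"vmax"`, `"ap_rise"`, `"cv"`).
#' @return A [fit_q10()] estimate.
#' @export
strand_feature_q10 <- function(sweep, feature = "apd90") {
  if (!feature %in% names(sweep)) stop("unknown feature", call. = FALSE)
  ref <- sweep[[feature]][sweep$temperature == 37]
  if (length(ref) != 1) stop("sweep must contain 37 degC", call. = FALSE)
  fit_q10(data.frame(temperature = sweep$temperature,
                     value = sweep[[feature]] / ref))
}

#' Calibrate a Q10 time-constant coefficient to a target feature Q10
#'
#' Optimises the shared per-feature-group coefficient (one scalar per cell
#' type, as in the model's coefficient table) so that the Q10 fitted to
#' the simulated strand feature-vs-temperature series equals the target.
#'
#' @param cell_type Cell type label.
#' @param feature One of `"APD90"` (group tau_si/tau_so/tau_w+), `"Vmax"`
#'   (tau_fi/tau_v+), `"CV"` (diffusion q10_D).
#' @param target_q10 Target fitted Q10 (> 0).
#' @param temperatures Temperature series for the fit.
#' @param bracket Search interval for the coefficient.
#' @param tol Tolerance on the fitted Q10.
#' @param ... Forwarded to [q10_strand_sweep()] (e.g. `dt`).
#' @return The calibrated coefficient, with attributes `fitted_q10` and
#'   `rmse`.
#' @export
calibrate_q10_tau <- function(cell_type, feature = c("APD90", "Vmax", "CV"),
                              target_q10, temperatures = seq(37, 27, -2),
                              bracket = c(0.1, 3), tol = 0.005, ...) {
  feature <- match.arg(feature)
  if (!is.finite(target_q10) || target_q10 <= 0) {
    stop("target Q10 must be positive", call. = FALSE)
  }
  col <- c(APD90 = "apd90", Vmax = "vmax", CV = "cv")[[feature]]
  grp <- c(APD90 = "q10_apd", Vmax = "q10_vmax", CV = "q10_D")[[feature]]
  fitted_at <- function(cc) {
    co <- q10_defaults()
    co[[grp]][co$cell_type == cryoEP::cell_type(cell_type)] <- cc
    sw <- q10_strand_sweep(cell_type, temperatures, coeffs = co, ...)
    strand_feature_q10(sw, col)
  }
  f <- function(cc) fitted_at(cc)$q10 - target_q10
  root <- uniroot(f, interval = bracket, tol = tol / 4, extendInt = "no")
  est <- fitted_at(root$root)
  if (abs(est$q10 - target_q10) > max(tol, 10 * abs(root$estim.prec))) {
    stop("calibration did not converge: fitted Q10 ", signif(est$q10, 4),
         " vs target ", target_q10, " (residual ",
         signif(est$q10 - target_q10, 3), ")", call. = FALSE)
  }
  structure(root$root, fitted_q10 = est$q10, rmse = est$rmse)
}
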