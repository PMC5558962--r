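## Linear-interpolated time at which `y` crosses `level` in the given
## direction, scanning from index `from`. Returns NA when never crossed.
.cross_time <- function(t, y, level, from = 1L, upward = TRUE) {
  n <- length(y)
  if (from >= n) return(NA_real_)
  yy <- y[from:n]
  tt <- t[from:n]
  hit <- if (upward) which(yy[-1] >= level & yy[-length(yy)] < level)
         else        which(yy[-1] <= level & yy[-length(yy)] > level)
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  frac <- (level - yy[i]) / (yy[i + 1] - yy[i])
  tt[i] + frac * (tt[i + 1] - tt[i])
}

#' Extract action-potential features from a single-beat trace
#'
#' Computes APD90 (interval from the 10% upstroke crossing to 90%
#' repolarisation), the maximum upstroke velocity Vmax (peak first
#' derivative of phase 0), the 10-90% upstroke time AP_rise, and -- when a
#' phase-1 notch is present -- the notch magnitude (phase-1 dip as % of the
#' phase-0 amplitude), notch duration (interval between the first two peaks
#' of the AP derivative) and notch index (magnitude x duration). Interval
#' features are invariant to uniform time shifts and amplitude scaling of
#' the trace.
#'
#' @param time Time base in ms (uniform sampling).
#' @param u Membrane trace (dimensionless u or mV), one complete AP with
#'   some quiescent baseline before the upstroke.
#' @param notch_window Search window after phase 0 for the notch, ms.
#' @return List of class `"ap_features"`: `apd90`, `vmax`, `ap_rise`
#'   (ms / trace-units per ms), `notch_magnitude` (%), `notch_duration`
#'   (ms), `notch_index` (% ms); notch fields `NA` when no notch is
#'   detected.
#' @export
extract_ap_features <- function(time, u, notch_window = 80) {
  if (length(time) != length(u) || length(u) < 8) {
    stop("need a sampled trace with matching time base", call. = FALSE)
  }
  dt <- diff(time[1:2])
  baseline <- u[1]
  peak_i <- which.max(u)
  amp <- u[peak_i] - baseline
  if (amp <= 0) stop("no action potential detected in trace", call. = FALSE)
  thr10 <- baseline + 0.1 * amp
  thr90 <- baseline + 0.9 * amp
  t10 <- .cross_time(time, u, thr10, upward = TRUE)
  if (is.na(t10)) stop("no action potential detected in trace", call. = FALSE)
  t90up <- .cross_time(time, u, thr90, upward = TRUE)
  # repolarisation: first downward crossing of the 10% level after the peak
  t_rep <- .cross_time(time, u, thr10, from = peak_i, upward = FALSE)
  if (is.na(t_rep)) stop("trace does not repolarise to 90%", call. = FALSE)
  dudt <- diff(u) / dt
  vmax <- max(dudt)

  # notch: a local minimum between two local maxima of u shortly after
  # phase 0; duration from the first two peaks of the derivative
  notch_mag <- notch_dur <- notch_idx <- NA_real_
  win <- which(time > time[peak_i] & time <= time[peak_i] + notch_window)
  if (length(win) > 4) {
    uw <- u[win]
    loc_min <- which(diff(sign(diff(uw))) > 0) + 1L
    if (length(loc_min)) {
      dip_i <- win[loc_min[which.min(uw[loc_min])]]
      after <- u[dip_i:min(length(u), dip_i + round(notch_window / dt))]
      dome <- max(after)
      if (dome > u[dip_i] + 1e-6 * amp) {
        notch_mag <- (u[peak_i] - u[dip_i]) / amp * 100
        # first two local maxima of du/dt: phase-0 upstroke and dome rise
        dpk <- which(diff(sign(diff(dudt))) < 0) + 1L
        dpk <- dpk[dudt[dpk] > 5e-4 * vmax]
        if (length(dpk) >= 2) {
          sep <- dpk[dpk > peak_i]          # second peak must follow phase 0
          if (length(sep)) {
            notch_dur <- time[sep[1]] - time[dpk[1]]
            notch_idx <- notch_mag * notch_dur
          }
        }
      }
    }
  }
  structure(list(
    apd90 = t_rep - t10, vmax = vmax, ap_rise = t90up - t10,
    notch_magnitude = notch_mag, notch_duration = notch_dur,
    notch_index = notch_idx
  ), class = "ap_features")
}

#' @export
print.ap_features <- function(x, ...) {
  cat(sprintf("APD90 %.1f ms | Vmax %.3g /ms | rise %.2f ms", x$apd90,
              x$vmax, x$ap_rise))
  if (!is.na(x$notch_magnitude)) {
    cat(sprintf(" | notch %.1f%% x %.1f ms", x$notch_magnitude,
                x$notch_duration))
  }
  cat("\n")
  invisible(x)
}

#' Transmural dispersion of repolarisation
#'
#' Time between the longest and the shortest APD along the transmural
#' profile.
#'
#' @param apd_profile Numeric vector of APD90 values (ms), e.g. along the
#'   central transmural line.
#' @return DOR in ms.
#' @export
#' @examples
#' dor(c(250, 290, 270))  # 40
dor <- function(apd_profile) {
  apd_profile <- apd_profile[!is.na(apd_profile)]
  if (length(apd_profile) < 2) stop("need at least two APDs", call. = FALSE)
  max(apd_profile) - min(apd_profile)
}

#' Extract ECG features from a pseudo-ECG beat
#'
#' Landmarks and intervals of a single transmural pseudo-ECG beat whose
#' time base starts at the stimulus onset: Q onset (first departure from
#' baseline exceeding 2% of the R amplitude), QRS duration (interval
#' between the maximal deflections of the Q and S waves), J-wave amplitude
#' (baseline to maximal J deflection after the QRS), T peak, and T end
#' (90% recurrence: first post-peak return to within 10% of the T
#' excursion above baseline). QT is Q onset to T end; TpTe is T peak to
#' T end.
#'
#' @param time Time base in ms, starting at stimulus onset.
#' @param amp pECG amplitude (trace units).
#' @param qrs_window Upper bound for QRS landmarks, ms; when the record
#'   carries an activation map, pass the latest activation time plus a
#'   margin.
#' @param j_window Search window for the J wave after the S wave, ms.
#' @param baseline_window Pre-Q window used for the baseline, ms.
#' @return List of class `"ecg_features"`: `qt`, `qrs`, `j_amplitude`,
#'   `tpte`, plus landmark times `t_q_onset`, `t_q`, `t_s`, `t_j`,
#'   `t_tpeak`, `t_tend` and `baseline`. Missing landmarks yield `NA`
#'   fields.
#' @export
extract_ecg_features <- function(time, amp, qrs_window = 150, j_window = 200,
                                 baseline_window = 50) {
  if (length(time) != length(amp) || length(amp) < 16) {
    stop("need a sampled pECG beat", call. = FALSE)
  }
  in_qrs <- time <= qrs_window
  r_i <- which.max(abs(amp - amp[1]) * in_qrs)
  # baseline: mean of the quiescent segment preceding the Q onset (up to
  # baseline_window ms; the trace starts at the stimulus onset, so the
  # available pre-Q segment may be shorter)
  t_on0 <- .cross_time(time, abs(amp - amp[1]),
                       0.02 * abs(amp[r_i] - amp[1]), upward = TRUE)
  if (is.na(t_on0)) t_on0 <- time[2]
  pre <- which(time < t_on0 & time >= t_on0 - baseline_window)
  base <- if (length(pre)) mean(amp[pre]) else amp[1]
  x <- amp - base
  r_amp <- x[r_i]

  t_q_onset <- .cross_time(time, abs(x), 0.02 * abs(r_amp), upward = TRUE)
  # Q and S: extrema of sign opposite to R before/after the R peak
  sgn <- sign(r_amp)
  qrs_i <- which(in_qrs)
  before <- qrs_i[qrs_i < r_i]
  after <- qrs_i[qrs_i > r_i]
  t_q <- if (length(before) && any(sgn * x[before] < 0)) {
    before[which.min(sgn * x[before])]
  } else NA_integer_
  t_s <- if (length(after) && any(sgn * x[after] < 0)) {
    after[which.min(sgn * x[after])]
  } else NA_integer_
  # monophasic fallback: Q onset / return toward baseline bound the complex
  qrs_start <- if (!is.na(t_q)) time[t_q] else t_q_onset
  qrs_end <- if (!is.na(t_s)) time[t_s] else {
    .cross_time(time, sgn * x, 0.1 * abs(r_amp), from = r_i, upward = FALSE)
  }
  qrs <- qrs_end - qrs_start

  # J wave: maximal positive deflection in the window after the QRS
  jw <- which(time > qrs_end & time <= qrs_end + j_window)
  t_j <- j_amp <- NA_real_
  if (length(jw)) {
    ji <- jw[which.max(x[jw])]
    t_j <- time[ji]
    j_amp <- x[ji]
  }
  # T wave: maximal absolute deflection after the J window
  tw <- which(time > qrs_end + j_window)
  t_tpeak <- t_tend <- qt <- tpte <- NA_real_
  if (length(tw)) {
    ti <- tw[which.max(abs(x[tw]))]
    t_tpeak <- time[ti]
    t_exc <- x[ti]
    t_tend <- .cross_time(time, sign(t_exc) * x, 0.1 * abs(t_exc),
                          from = ti, upward = FALSE)
    if (!is.na(t_tend) && !is.na(t_q_onset)) qt <- t_tend - t_q_onset
    if (!is.na(t_tend)) tpte <- t_tend - t_tpeak
  }
  structure(list(
    qt = qt, qrs = qrs, j_amplitude = j_amp, tpte = tpte,
    t_q_onset = t_q_onset, t_q = qrs_start, t_s = qrs_end, t_j = t_j,
    t_tpeak = t_tpeak, t_tend = t_tend, baseline = base
  ), class = "ecg_features")
}

#' @export
print.ecg_features <- function(x, ...) {
  cat(sprintf("QT %.1f ms | QRS %.1f ms | J %.4g | TpTe %.1f ms\n",
              x$qt, x$qrs, x$j_amplitude, x$tpte))
  invisible(x)
}

#' Conduction velocity from the gradient of an activation map
#'
#' `CV = 1/|grad t|` using central differences of the wavefront arrival
#' time on the regular grid (one-sided at boundaries). Nodes whose
#' neighbourhood is not fully activated, or where the local gradient
#' vanishes (infinite-speed guard), are returned as `NA`.
#'
#' @param act Activation times (ms) in node order.
#' @param geometry A [wedge_geometry()] object (or list with `dims`, `ds`).
#' @return Per-node CV in cm/s, same shape as `act`.
#' @export
cv_from_activation_map <- function(act, geometry) {
  dims <- geometry$dims
  ds <- geometry$ds
  a <- array(act, dim = dims)
  grad2 <- array(0, dim = dims)
  for (ax in which(dims > 1)) {
    n <- dims[ax]
    hi <- lapply(dims, seq_len)
    lo <- hi
    hi[[ax]] <- pmin(hi[[ax]] + 1L, n)
    lo[[ax]] <- pmax(lo[[ax]] - 1L, 1L)
    fwd <- do.call(`[`, c(list(a), hi, list(drop = FALSE)))
    bwd <- do.call(`[`, c(list(a), lo, list(drop = FALSE)))
    span <- (hi[[ax]] - lo[[ax]]) * ds      # 2 ds interior, ds at faces
    g <- (fwd - bwd) / array(span[slice.index(a, ax)], dims)
    grad2 <- grad2 + g^2
  }
  cv <- 1 / sqrt(grad2) * 1000      # cm/ms -> cm/s
  cv[!is.finite(cv)] <- NA_real_
  cv
}
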