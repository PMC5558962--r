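#' Regenerate the model's quantitative summary tables
#'
#' Re-runs the cooling experiment (37 down to 27 degC in 2 degC steps by
#' default) at the requested scale and emits the summary table behind the
#' corresponding figure of the study design:
#' \describe{
#'   \item{`"apd"`}{APD90 (and Vmax, AP_rise, CV) per cell type and
#'     temperature from the 1D strand protocol, with fitted Q10s.}
#'   \item{`"intervals"`}{QT, QRS, DOR, TpTe per temperature from the
#'     wedge (slice or 3D block) pseudo-ECG.}
#'   \item{`"jwave"`}{J-wave amplitude and epicardial notch features per
#'     temperature, with the temperature and notch correlations.}
#'   \item{`"gap"`}{QT with and without gap-junction temperature
#'     dependence per temperature (conduction-slowing contribution).}
#' }
#'
#' @param table One of `"apd"`, `"intervals"`, `"jwave"`, `"gap"`.
#' @param scale `"strand1d"`, `"slice2d"` or `"full3d"`. The 3D block at
#'   reference resolution is a long run and must be opted into with
#'   `allow_long = TRUE`.
#' @param temperatures Temperatures in degC.
#' @param cl_mode `"fixed"` or `"q10"`.
#' @param ds,dt Wedge resolution (ignored for `"strand1d"`).
#' @param allow_long Opt-in for `scale = "full3d"`.
#' @param quiet Suppress progress messages.
#' @return A data frame; correlation/fit summaries are attached as
#'   attributes where applicable.
#' @export
reproduce_tables <- function(table = c("apd", "intervals", "jwave", "gap"),
                             scale = c("slice2d", "strand1d", "full3d"),
                             temperatures = seq(37, 27, by = -2),
                             cl_mode = "fixed", ds = 0.02, dt = 0.02,
                             allow_long = FALSE, quiet = FALSE) {
  table <- match.arg(table)
  scale <- match.arg(scale)
  if (scale == "full3d" && !allow_long) {
    stop("a full-3D run at this resolution takes hours on one CPU; ",
         "pass allow_long = TRUE to proceed or use scale = 'slice2d'",
         call. = FALSE)
  }
  say <- function(...) if (!quiet) message(...)

  if (table == "apd" || scale == "strand1d") {
    rows <- list()
    fits <- list()
    for (ct in CELL_TYPES) {
      say("strand sweep: ", ct)
      sw <- q10_strand_sweep(ct, temperatures, cl = if (cl_mode == "q10")
        "q10" else 1000)
      sw$cell_type <- ct
      rows[[ct]] <- sw
      fits[[ct]] <- vapply(c("apd90", "vmax", "ap_rise", "cv"),
                           function(f) strand_feature_q10(sw, f)$q10,
                           numeric(1))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "fitted_q10") <- do.call(rbind, fits)
    return(out)
  }

  runs <- lapply(temperatures, function(temp) {
    say("wedge run: ", temp, " degC")
    wedge_features(run_wedge(temp, cl_mode = cl_mode, scale = scale,
                             ds = ds, dt = dt))
  })
  if (table == "intervals") {
    out <- data.frame(
      temperature = temperatures,
      qt = vapply(runs, function(r) r$ecg$qt, numeric(1)),
      qrs = vapply(runs, function(r) r$ecg$qrs, numeric(1)),
      dor = vapply(runs, function(r) r$dor, numeric(1)),
      tpte = vapply(runs, function(r) r$ecg$tpte, numeric(1))
    )
    attr(out, "qrs_slope_ms_per_degC") <-
      -unname(coef(lm(qrs ~ temperature, data = out))[2])
    return(out)
  }
  if (table == "jwave") {
    out <- data.frame(
      temperature = temperatures,
      j_amplitude = vapply(runs, function(r) r$ecg$j_amplitude, numeric(1)),
      notch_magnitude = vapply(runs, function(r) r$notch$notch_magnitude,
                               numeric(1)),
      notch_duration = vapply(runs, function(r) r$notch$notch_duration,
                              numeric(1)),
      notch_index = vapply(runs, function(r) r$notch$notch_index,
                           numeric(1))
    )
    attr(out, "r_temperature") <- stats::cor(out$temperature, out$j_amplitude)
    attr(out, "r_notch") <- stats::cor(out$notch_magnitude, out$j_amplitude)
    return(out)
  }
  # gap: conduction-slowing contribution to QT
  qt_off <- vapply(temperatures, function(temp) {
    say("wedge run (gap junctions fixed at 37 degC): ", temp, " degC")
    wedge_features(run_wedge(temp, cl_mode = cl_mode, scale = scale,
                             ds = ds, dt = dt, gap_q10 = FALSE))$ecg$qt
  }, numeric(1))
  data.frame(
    temperature = temperatures,
    qt_full = vapply(runs, function(r) r$ecg$qt, numeric(1)),
    qt_gap_off = qt_off,
    delta_qt = vapply(runs, function(r) r$ecg$qt, numeric(1)) - qt_off
  )
}
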