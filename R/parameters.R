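#' @useDynLib cryoEP, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef lm median nls optimize rlnorm uniroot
NULL

## Canonical cell-type labels. Every parameter set, grid node and protocol
## references exactly one of these.
CELL_TYPES <- c("EPI", "M", "ENDO")

#' Validate and normalise a cell-type label
#'
#' @param cell_type One of `"EPI"`, `"M"`, `"ENDO"` (case-insensitive).
#' @return The normalised label.
#' @export
#' @examples
#' cell_type("epi")
cell_type <- function(cell_type) {
  ct <- toupper(as.character(cell_type[1]))
  if (!ct %in% CELL_TYPES) {
    stop("unknown cell type '", cell_type, "'; must be one of ",
         paste(CELL_TYPES, collapse = ", "), call. = FALSE)
  }
  ct
}

## Base parameter sets of the four-variable minimal ventricular (MV) model
## for human epicardial, midmyocardial and endocardial cells (Bueno-Orovio,
## Cherry & Fenton 2008, J Theor Biol 253:544-560, Table 1). Times in ms,
## voltages dimensionless. These are the 37 degC, cAPD = 1 reference values.
.mv_param_names <- c(
  "u_o", "u_u", "theta_v", "theta_w", "theta_vminus", "theta_o",
  "tau_v1minus", "tau_v2minus", "tau_vplus",
  "tau_w1minus", "tau_w2minus", "k_wminus", "u_wminus", "tau_wplus",
  "tau_fi", "tau_o1", "tau_o2", "tau_so1", "tau_so2", "k_so", "u_so",
  "tau_s1", "tau_s2", "k_s", "u_s", "tau_si", "tau_winf", "w_inf_star"
)

.mv_base <- list(
  EPI = c(
    u_o = 0, u_u = 1.55, theta_v = 0.3, theta_w = 0.13,
    theta_vminus = 0.006, theta_o = 0.006,
    tau_v1minus = 60, tau_v2minus = 1150, tau_vplus = 1.4506,
    tau_w1minus = 60, tau_w2minus = 15, k_wminus = 65, u_wminus = 0.03,
    tau_wplus = 200,
    tau_fi = 0.11, tau_o1 = 400, tau_o2 = 6,
    tau_so1 = 30.0181, tau_so2 = 0.9957, k_so = 2.0458, u_so = 0.65,
    tau_s1 = 2.7342, tau_s2 = 16, k_s = 2.0994, u_s = 0.9087,
    tau_si = 1.8875, tau_winf = 0.07, w_inf_star = 0.94
  ),
  M = c(
    u_o = 0, u_u = 1.61, theta_v = 0.3, theta_w = 0.13,
    theta_vminus = 0.1, theta_o = 0.005,
    tau_v1minus = 80, tau_v2minus = 1.4506, tau_vplus = 1.4506,
    tau_w1minus = 70, tau_w2minus = 8, k_wminus = 200, u_wminus = 0.016,
    tau_wplus = 280,
    tau_fi = 0.078, tau_o1 = 410, tau_o2 = 7,
    tau_so1 = 91, tau_so2 = 0.8, k_so = 2.1, u_so = 0.6,
    tau_s1 = 2.7342, tau_s2 = 4, k_s = 2.0994, u_s = 0.9087,
    tau_si = 3.3849, tau_winf = 0.01, w_inf_star = 0.5
  ),
  ENDO = c(
    u_o = 0, u_u = 1.56, theta_v = 0.3, theta_w = 0.13,
    theta_vminus = 0.2, theta_o = 0.006,
    tau_v1minus = 75, tau_v2minus = 10, tau_vplus = 1.4506,
    tau_w1minus = 6, tau_w2minus = 140, k_wminus = 200, u_wminus = 0.016,
    tau_wplus = 280,
    tau_fi = 0.1, tau_o1 = 470, tau_o2 = 6,
    tau_so1 = 40, tau_so2 = 1.2, k_so = 2, u_so = 0.65,
    tau_s1 = 2.7342, tau_s2 = 2, k_s = 2.0994, u_s = 0.9087,
    tau_si = 2.9013, tau_winf = 0.0273, w_inf_star = 0.78
  )
)

## Time constants (subset of the parameter vector) by scaling group.
.tau_group <- list(
  capd  = c("tau_wplus", "tau_si", "tau_so1", "tau_so2"),
  apd   = c("tau_si", "tau_so1", "tau_so2", "tau_wplus"),
  vmax  = c("tau_fi", "tau_vplus"),
  notch = c("tau_s1", "tau_s2")
)

#' Base minimal-model parameter set for one cell type
#'
#' Returns the unmodified (37 degC, no APD-ratio correction) constant set of
#' the four-variable minimal ventricular model for an epicardial,
#' midmyocardial or endocardial cell. Times are in ms; thresholds, slopes
#' and the membrane variable are dimensionless.
#'
#' @param ct Cell type label (`"EPI"`, `"M"`, `"ENDO"`).
#' @return A named numeric vector of class `"mv_parameters"` with
#'   attributes `cell_type` and `temperature`.
#' @export
#' @examples
#' p <- mv_parameters("EPI")
#' p[["tau_si"]]
mv_parameters <- function(ct) {
  ct <- cell_type(ct)
  p <- .mv_base[[ct]]
  structure(p, class = "mv_parameters", cell_type = ct, temperature = 37)
}

#' @export
print.mv_parameters <- function(x, ...) {
  cat("Minimal ventricular model parameters\n")
  cat("  cell type:  ", attr(x, "cell_type"), "\n")
  cat("  temperature:", attr(x, "temperature"), "degC\n")
  print(unclass(x))
  invisible(x)
}

#' Default Q10 temperature coefficients
#'
#' The calibrated Q10 coefficients per cell type: `q10_apd` scales the
#' APD-controlling time constants (tau_si, tau_so, tau_w+), `q10_vmax` the
#' upstroke constants (tau_fi, tau_v+), `q10_notch` the s-gate constants
#' (tau_s), and `q10_D` the gap-junction diffusion coefficient. `q10_cl`
#' (0.28, shared) governs the temperature-adapted cycle length.
#'
#' @return A data frame with one row per cell type and the component `q10_cl`
#'   attached as an attribute.
#' @export
q10_defaults <- function() {
  out <- data.frame(
    cell_type = c("EPI", "M", "ENDO"),
    q10_apd   = c(0.69, 0.53, 0.58),
    q10_vmax  = c(0.57, 0.67, 0.60),
    q10_notch = c(0.24, 0.53, 0.58),
    q10_D     = c(1.35, 1.39, 1.40),
    stringsAsFactors = FALSE
  )
  attr(out, "q10_cl") <- 0.28
  out
}

#' Default APD-ratio correction factors (cAPD)
#'
#' Multiplicative correction of the repolarisation time constants
#' (tau_w+, tau_si, tau_so) that restores the physiological transmural APD
#' ratios (M:endo about 1.04, M:epi about 1.3) in electrotonically coupled
#' tissue: 1.05 for epicardial, 1.40 for endocardial, 1 for M cells.
#'
#' @return Named numeric vector with elements `EPI`, `M`, `ENDO`.
#' @export
capd_defaults <- function() c(EPI = 1.05, M = 1.0, ENDO = 1.40)

#' Q10 temperature scaling of a positive quantity
#'
#' Applies the Q10 law `x(T) = x_ref * q10^((T - T_ref)/10)`. For q10 < 1
#' the quantity grows on cooling (e.g. time constants, cycle length); for
#' q10 > 1 it shrinks (e.g. diffusion).
#'
#' @param x_ref Reference value at `T_ref` (> 0).
#' @param q10 Temperature coefficient (> 0).
#' @param temperature Temperature in degC (20-40).
#' @param t_ref Reference temperature in degC, default 37.
#' @return The scaled quantity; identical to `x_ref` at `T = T_ref`.
#' @export
#' @examples
#' temperature_scale(100, 0.69, 27)  # 100/0.69 ~ 144.9 ms
temperature_scale <- function(x_ref, q10, temperature, t_ref = 37) {
  if (any(!is.finite(x_ref)) || any(x_ref <= 0)) {
    stop("x_ref must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(q10)) || any(q10 <= 0)) {
    stop("q10 must be positive and finite", call. = FALSE)
  }
  if (any(temperature < 20) || any(temperature > 40)) {
    stop("temperature must lie in [20, 40] degC", call. = FALSE)
  }
  x_ref * q10^((temperature - t_ref) / 10)
}

#' Apply the APD-ratio correction to a parameter set
#'
#' Multiplies tau_w+, tau_si and both outward-current time constants
#' (tau_so1, tau_so2) by the cell type's cAPD factor; all other constants
#' are unchanged.
#'
#' @param params An `mv_parameters` vector.
#' @param factors Named factor vector as from [capd_defaults()].
#' @return The corrected parameter set.
#' @export
apply_capd <- function(params, factors = capd_defaults()) {
  ct <- attr(params, "cell_type")
  if (is.null(ct) || !ct %in% names(factors)) {
    stop("parameter set has no valid cell type", call. = FALSE)
  }
  f <- factors[[ct]]
  if (!is.finite(f) || f <= 0) stop("invalid cAPD factor", call. = FALSE)
  params[.tau_group$capd] <- params[.tau_group$capd] * f
  params
}

#' Build the full temperature-scaled parameter set for one cell type
#'
#' Applies the APD-ratio correction first, then Q10 scaling of the three
#' time-constant groups: `q10_apd` to (tau_si, tau_so1, tau_so2, tau_w+),
#' `q10_vmax` to (tau_fi, tau_v+) and `q10_notch` to (tau_s1, tau_s2).
#' Both steps are multiplicative so their order is cosmetic; it is fixed
#' for reproducibility. At 37 degC the result equals the cAPD-corrected
#' base set.
#'
#' @param ct Cell type label.
#' @param temperature Temperature in degC (20-40).
#' @param coeffs Q10 coefficient table as from [q10_defaults()].
#' @param factors cAPD factors as from [capd_defaults()].
#' @return An `mv_parameters` vector with attribute `temperature` set.
#' @export
#' @examples
#' p27 <- build_cell_parameters("EPI", 27)
#' p37 <- build_cell_parameters("EPI", 37)
#' p27[["tau_si"]] / p37[["tau_si"]]  # = 1/0.69
build_cell_parameters <- function(ct, temperature = 37,
                                  coeffs = q10_defaults(),
                                  factors = capd_defaults()) {
  ct <- cell_type(ct)
  p <- apply_capd(mv_parameters(ct), factors)
  row <- coeffs[coeffs$cell_type == ct, , drop = FALSE]
  if (nrow(row) != 1) stop("no Q10 coefficients for cell type ", ct, call. = FALSE)
  for (grp in c("apd", "vmax", "notch")) {
    q <- row[[paste0("q10_", grp)]]
    p[.tau_group[[grp]]] <-
      temperature_scale(p[.tau_group[[grp]]], q, temperature)
  }
  attr(p, "temperature") <- temperature
  p
}

#' Temperature-adapted pacing cycle length
#'
#' `CL(T) = 1000 ms * 0.28^((T - 37)/10)`: the cycle length grows as the
#' tissue cools (Q10 of the beating rate is 0.28).
#'
#' @param temperature Temperature in degC (20-40).
#' @param q10_cl Cycle-length temperature coefficient, default 0.28.
#' @param cl_ref Reference cycle length at 37 degC (ms).
#' @return Cycle length in ms.
#' @export
#' @examples
#' adapt_cycle_length(27)  # 1000/0.28 ~ 3571 ms
adapt_cycle_length <- function(temperature, q10_cl = 0.28, cl_ref = 1000) {
  temperature_scale(cl_ref, q10_cl, temperature)
}

## Affine rescaling of the dimensionless membrane variable to mV
## (Bueno-Orovio et al. 2008): V = 85.7 u - 84.
.mv_volt_gain <- 85.7
.mv_volt_offset <- -84

#' Map the dimensionless membrane variable to mV (and back)
#'
#' The affine rescaling `V = 85.7 u - 84` mV; rest (u = 0) maps to the
#' resting potential of -84 mV.
#'
#' @param u Dimensionless membrane variable.
#' @return Membrane potential in mV.
#' @export
#' @examples
#' map_u_to_mV(0)   # -84
#' map_mV_to_u(map_u_to_mV(0.5))
map_u_to_mV <- function(u) .mv_volt_gain * u + .mv_volt_offset

#' @rdname map_u_to_mV
#' @param v_mV Membrane potential in mV.
#' @export
map_mV_to_u <- function(v_mV) (v_mV - .mv_volt_offset) / .mv_volt_gain
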