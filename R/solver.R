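## Internal wrapper around the compiled monodomain stepper. All node
## indices are 0-based at this boundary; `tensors` are in cm^2/ms.
.mono_run_raw <- function(dims, ds, tensors, ctype, params, state,
                          stim_nodes, stim_amp, stim_dur, stim_times,
                          duration, dt, trace_nodes = integer(0),
                          trace_stride = 0L, act_threshold = 0.3,
                          ecg = NULL, reaction_on = TRUE) {
  cpp_mono_run(
    state$u, state$v, state$w, state$s,
    as.integer(dims), ds, tensors, as.integer(ctype), params,
    as.integer(stim_nodes), stim_amp, stim_dur, as.numeric(stim_times),
    duration, dt, as.integer(trace_nodes), as.integer(trace_stride),
    act_threshold,
    if (is.null(ecg)) NULL else ecg$h_epi,
    if (is.null(ecg)) NULL else ecg$h_endo,
    if (is.null(ecg)) 0L else as.integer(ecg$stride),
    reaction_on
  )
}

#' Discrete divergence of the anisotropic diffusion flux
#'
#' Applies the solver's conservative finite-difference approximation of
#' `div(D grad u)` on a regular grid with no-flux boundaries, handling
#' spatially varying anisotropic tensors (face-averaged conductivities with
#' cross-derivative terms). For homogeneous isotropic tensors it reduces to
#' the standard 7-point Laplacian.
#'
#' @param field Numeric array (or vector in node order) of the scalar field.
#' @param tensors N x 6 matrix of tensor components
#'   (xx, yy, zz, xy, xz, yz) in cm^2/s, one row per node.
#' @param geometry A [wedge_geometry()] object (or any list with `dims` and
#'   `ds`).
#' @return Numeric vector, `div(D grad u)` per node in 1/s units of `field`
#'   per unit time (cm^2/s input gives 1/s; divide by 1000 for 1/ms).
#' @export
anisotropic_divergence <- function(field, tensors, geometry) {
  dims <- geometry$dims
  if (length(field) != prod(dims)) {
    stop("field length does not match geometry", call. = FALSE)
  }
  cpp_aniso_div(as.numeric(field), as.integer(dims), geometry$ds, tensors)
}

#' Per-node activation map of the analysis beat
#'
#' Activation is the first upward crossing of the threshold (u = 0.3,
#' well above the notch region and below the plateau) by the membrane
#' variable; the solver records crossings on the fly with linear sub-step
#' interpolation. Unactivated nodes are `NA`.
#'
#' @param record A simulation record (from [run_strand()] or
#'   [run_wedge()]).
#' @return Numeric vector of activation times in ms relative to the
#'   analysis beat's stimulus onset, in node order; `NA` for unactivated
#'   nodes. Reshape with the geometry's `dims` for 2D/3D maps (e.g. for
#'   [cv_from_activation_map()]).
#' @export
activation_map <- function(record) {
  act <- record$act
  if (is.null(act)) stop("record has no activation data", call. = FALSE)
  act
}
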