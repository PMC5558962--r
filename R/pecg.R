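#' Transmural bipolar electrode setup
#'
#' Places the two virtual electrodes on the transmural axis through the
#' block centre, `distance` outside the epicardial (z = 0) and endocardial
#' (z = lz) faces. Electrodes must lie outside the tissue.
#'
#' @param geometry A [build_wedge()] object.
#' @param distance Electrode-to-surface distance, cm (default 1 cm).
#' @return List of class `"electrode_setup"` with `epi` and `endo`
#'   positions (cm, c(x, y, z)).
#' @export
electrode_setup <- function(geometry, distance = 1.0) {
  if (distance <= 0) {
    stop("electrodes must be outside the tissue (distance > 0)",
         call. = FALSE)
  }
  cx <- geometry$lx / 2
  cy <- if (geometry$dims[2] == 1L) 0 else geometry$ly / 2
  structure(list(
    epi = c(cx, cy, -distance),
    endo = c(cx, cy, geometry$lz + distance)
  ), class = "electrode_setup")
}

## Internal: per-node lead-field weight vectors h = D grad(1/r) for one
## electrode (N x 3, using the anisotropic tensor in cm^2/s; the overall
## proportionality constant k is set to 1, so only ratios and intervals of
## the pECG are meaningful). For a 2D transmural slice the weights are
## integrated over the virtual transverse (y) extent of the block the
## slice stands for, i.e. the sources are treated as y-uniform over `ly`;
## this reproduces the depth weighting of the 3D electrode geometry.
.lead_field_weights <- function(geometry, tensors, electrode) {
  dims <- geometry$dims
  slice <- dims[2] == 1L
  yv <- if (slice) {
    ly <- if (is.null(geometry$ly) || geometry$ly <= 0) 2 else geometry$ly
    seq(-ly / 2, ly / 2, by = geometry$ds)
  } else geometry$y
  coords <- expand.grid(x = geometry$x, y = if (slice) 0 else yv,
                        z = geometry$z)
  acc <- matrix(0, nrow(coords), 3)
  for (ye in if (slice) yv else 0) {
    dx <- coords$x - electrode[1]
    dy <- coords$y + ye - electrode[2]
    dz <- coords$z - electrode[3]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    if (any(r < geometry$ds / 2)) {
      stop("electrode inside the tissue", call. = FALSE)
    }
    acc <- acc + cbind(-dx / r^3, -dy / r^3, -dz / r^3)   # grad_node (1/r)
  }
  g <- acc / (if (slice) length(yv) else 1)
  cbind(
    tensors[, "xx"] * g[, 1] + tensors[, "xy"] * g[, 2] + tensors[, "xz"] * g[, 3],
    tensors[, "xy"] * g[, 1] + tensors[, "yy"] * g[, 2] + tensors[, "yz"] * g[, 3],
    tensors[, "xz"] * g[, 1] + tensors[, "yz"] * g[, 2] + tensors[, "zz"] * g[, 3]
  )
}

#' Unipolar lead-field potential of a membrane-potential snapshot
#'
#' Evaluates the dipole-source sum
#' `phi = k * sum_nodes [-(D grad V) . grad(1/r)] dV` for one electrode
#' position, with V in mV and the local anisotropic tensor; k = 1.
#'
#' @param u Membrane variable field (dimensionless, node order).
#' @param tensors N x 6 tensor matrix (cm^2/s).
#' @param geometry A [build_wedge()] object.
#' @param electrode Electrode position, cm, `c(x, y, z)`; must be outside
#'   the tissue.
#' @return Potential in arbitrary units proportional to mV.
#' @export
unipolar_potential <- function(u, tensors, geometry, electrode) {
  h <- .lead_field_weights(geometry, tensors, electrode)
  cpp_lead_field(as.numeric(u), as.integer(geometry$dims), geometry$ds, h)
}

## Bipolar polarity: phi(epi electrode) - phi(endo electrode), with a fixed
## sign chosen once so that the J and T waves of the 37 degC default block
## are positive.
.pecg_polarity <- 1

#' Bipolar transmural pseudo-ECG of a simulated beat
#'
#' Returns the bipolar trace (epicardial minus endocardial unipolar
#' potential) of a wedge simulation, sampled at 1 kHz, with the sign
#' convention that makes the 37 degC J and T waves positive.
#'
#' @param record A [run_wedge()] record.
#' @return Data frame of class `"pecg_trace"` with columns `time` (ms) and
#'   `amp` (arbitrary units proportional to mV).
#' @export
bipolar_pecg <- function(record) {
  if (is.null(record$ecg)) {
    stop("record carries no pECG recording", call. = FALSE)
  }
  out <- data.frame(time = record$ecg$time,
                    amp = .pecg_polarity * (record$ecg$phi_epi -
                                              record$ecg$phi_endo))
  class(out) <- c("pecg_trace", class(out))
  out
}
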