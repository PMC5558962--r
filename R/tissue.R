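#' Reference conduction velocities and diffusion coefficients at 37 degC
#'
#' Per cell type: calibrated diffusion coefficients (cm^2/s) in the
#' longitudinal (fiber), transverse (in-sheet, normal to fiber) and
#' transmural (endo-to-epi) directions, together with the conduction
#' velocities (cm/s) they reproduce on a 1D strand at the reference
#' resolution (ds = 0.2 mm, dt = 0.01 ms).
#'
#' @return Data frame with one row per cell type.
#' @export
diffusion_defaults <- function() {
  data.frame(
    cell_type    = c("EPI", "M", "ENDO"),
    D_long       = c(0.692, 0.764, 0.900),
    D_trans      = c(0.214, 0.236, 0.255),
    D_transmural = c(0.102, 0.124, 0.124),
    cv_long      = c(54, 67, 67),
    cv_trans     = c(25, 30, 30),
    cv_transmural = c(13.8, 17.3, 17.3),
    stringsAsFactors = FALSE
  )
}

#' Temperature scaling of a diffusion coefficient
#'
#' `D(T) = D37 * q10_D^((T - 37)/10)`: diffusion (gap-junction coupling)
#' decreases as the tissue cools (q10_D > 1). With the gap-junction
#' temperature switch off the coefficient is returned unchanged, which
#' isolates the cellular (kinetic) contribution to cooling effects.
#'
#' @param D37 Diffusion coefficient at 37 degC (cm^2/s, > 0).
#' @param q10_D Temperature coefficient of D (> 0).
#' @param temperature Temperature in degC.
#' @param gap_q10 Logical; `FALSE` switches the temperature dependence of
#'   the gap junctions off.
#' @return Scaled diffusion coefficient, cm^2/s.
#' @export
#' @examples
#' scale_diffusion(0.9, 1.40, 27)         # 0.9/1.40
#' scale_diffusion(0.9, 1.40, 27, FALSE)  # 0.9
scale_diffusion <- function(D37, q10_D, temperature, gap_q10 = TRUE) {
  if (any(D37 <= 0) || any(q10_D <= 0)) {
    stop("D37 and q10_D must be positive", call. = FALSE)
  }
  if (!gap_q10) return(D37)
  temperature_scale(D37, q10_D, temperature)
}

#' Build the wedge geometry: grid, cell-type layers and fiber field
#'
#' Constructs the regular node-centred grid of the ventricular block
#' (default 2 x 2 x 1 cm at ds = 0.02 cm), assigns transmural layers
#' occupying 10% (epicardial), 30% (midmyocardial) and 60% (endocardial)
#' of the wall thickness measured from the epicardial face (z = 0), and a
#' helical fiber field rotating linearly from -60 deg at the epicardial
#' face to +60 deg at the endocardial face (angles in the x-y plane,
#' constant within each plane).
#'
#' @param lx,ly,lz Extents in cm (x longitudinal, y transverse,
#'   z transmural). `ly = 0` builds a 2D transmural slice (x-z plane).
#' @param ds Node spacing in cm.
#' @param layers Named fractions of wall thickness, epicardial face first;
#'   must sum to 1.
#' @param theta_range Fiber angles (deg) at the epicardial and endocardial
#'   faces.
#' @return An object of class `"wedge_geometry"`: list with `dims`, `ds`,
#'   node coordinate vectors `x`, `y`, `z`, per-node `cell_type` (factor
#'   levels EPI/M/ENDO in node order) and `theta` (deg).
#' @export
#' @examples
#' g <- build_wedge(ds = 0.1)
#' g$dims
build_wedge <- function(lx = 2, ly = 2, lz = 1, ds = 0.02,
                        layers = c(EPI = 0.1, M = 0.3, ENDO = 0.6),
                        theta_range = c(-60, 60)) {
  if (abs(sum(layers) - 1) > 1e-9) {
    stop("layer fractions must sum to 1", call. = FALSE)
  }
  nx <- round(lx / ds) + 1L
  ny <- if (ly <= 0) 1L else round(ly / ds) + 1L
  nz <- round(lz / ds) + 1L
  x <- (seq_len(nx) - 1L) * ds
  y <- (seq_len(ny) - 1L) * ds
  z <- (seq_len(nz) - 1L) * ds
  frac <- z / lz
  layer_of_frac <- function(f) {
    cuts <- cumsum(layers)           # (0.1, 0.4, 1.0) from the epi face
    ifelse(f < cuts[1], names(layers)[1],
           ifelse(f < cuts[2], names(layers)[2], names(layers)[3]))
  }
  ct_z <- layer_of_frac(frac)
  theta_z <- theta_range[1] + (theta_range[2] - theta_range[1]) * frac
  # node order: x fastest, then y, then z
  ct <- factor(rep(ct_z, each = nx * ny), levels = CELL_TYPES)
  theta <- rep(theta_z, each = nx * ny)
  structure(
    list(dims = c(nx, ny, nz), ds = ds, lx = lx, ly = ly, lz = lz,
         x = x, y = y, z = z, cell_type = ct, theta = theta,
         layers = layers),
    class = "wedge_geometry"
  )
}

#' @export
print.wedge_geometry <- function(x, ...) {
  cat("Wedge geometry: ", paste(x$dims, collapse = " x "),
      " nodes at ds = ", x$ds, " cm\n", sep = "")
  cat("  layers (from epicardial face z = 0): ",
      paste(sprintf("%s %.0f%%", names(x$layers), 100 * x$layers),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-node anisotropic diffusion tensors
#'
#' Builds the symmetric 3 x 3 diffusion tensor for every node from the
#' node's cell-type directional coefficients (longitudinal, transverse,
#' transmural; see [diffusion_defaults()]) rotated by the local fiber
#' angle about the transmural (z) axis, then temperature-scaled per cell
#' type. The transmural value is pinned to the z-axis regardless of fiber
#' angle.
#'
#' @param geometry A [build_wedge()] object.
#' @param temperature Temperature in degC.
#' @param coeffs Q10 coefficient table ([q10_defaults()]); column `q10_D`
#'   is used.
#' @param dtable Directional coefficients ([diffusion_defaults()]).
#' @param gap_q10 Logical; `FALSE` freezes D at its 37 degC value.
#' @return N x 6 matrix with columns `xx, yy, zz, xy, xz, yz` in cm^2/s.
#' @export
diffusion_tensors <- function(geometry, temperature = 37,
                              coeffs = q10_defaults(),
                              dtable = diffusion_defaults(),
                              gap_q10 = TRUE) {
  ct <- as.character(geometry$cell_type)
  m <- match(ct, dtable$cell_type)
  q <- coeffs$q10_D[match(ct, coeffs$cell_type)]
  DL <- scale_diffusion(dtable$D_long[m], q, temperature, gap_q10)
  DT <- scale_diffusion(dtable$D_trans[m], q, temperature, gap_q10)
  DZ <- scale_diffusion(dtable$D_transmural[m], q, temperature, gap_q10)
  th <- geometry$theta * pi / 180
  c2 <- cos(th)^2
  s2 <- sin(th)^2
  sc <- sin(th) * cos(th)
  cbind(
    xx = DL * c2 + DT * s2,
    yy = DL * s2 + DT * c2,
    zz = DZ,
    xy = (DL - DT) * sc,
    xz = 0,
    yz = 0
  )
}

## Internal: 0-based node indices of the default stimulus patch -- a small
## patch at the middle of the left (x = 0) edge of the endocardial face
## (z = lz), `depth` nodes deep in each available dimension.
.stim_patch <- function(geometry, depth = 3L) {
  dims <- geometry$dims
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  ii <- seq_len(min(depth, nx)) - 1L
  kk <- nz - seq_len(min(depth, nz))
  if (ny == 1L) {
    jj <- 0L
  } else {
    mid <- (ny - 1L) %/% 2L
    jj <- unique(pmin(pmax(mid + (-1L:1L), 0L), ny - 1L))
  }
  as.integer(outer(ii, outer(jj * nx, kk * nx * ny, "+"), "+"))
}
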