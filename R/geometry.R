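#' Voxel geometry of an acquisition
#'
#' Records the physical size of a voxel: the lateral pixel size and the
#' z-step between optical sections, both in micrometres.  Every conversion
#' between physical lengths and voxel counts in the package goes through
#' these two factors.
#'
#' @param pixel_size_xy Lateral pixel size in µm/pixel (> 0).
#' @param z_step Axial spacing between slices in µm/slice (> 0).
#' @return An object of class `voxel_geometry`.
#' @examples
#' voxel_geometry(0.55, 0.3)
#' @export
voxel_geometry <- function(pixel_size_xy, z_step) {
  stopifnot(is.numeric(pixel_size_xy), length(pixel_size_xy) == 1,
            is.numeric(z_step), length(z_step) == 1)
  if (!is.finite(pixel_size_xy) || pixel_size_xy <= 0)
    stop("`pixel_size_xy` must be a strictly positive length in um")
  if (!is.finite(z_step) || z_step <= 0)
    stop("`z_step` must be a strictly positive length in um")
  structure(list(pixel_size_xy = as.numeric(pixel_size_xy),
                 z_step = as.numeric(z_step)),
            class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("<voxel_geometry> pixel_size_xy = %g um, z_step = %g um\n",
              x$pixel_size_xy, x$z_step))
  invisible(x)
}

#' Convert a physical length to a voxel count along one axis
#'
#' Lengths in µm are converted to voxels by dividing by the per-axis voxel
#' size and rounding half away from zero, so a threshold stated in µm maps
#' to the nearest whole number of voxels on each (anisotropic) axis.
#'
#' @param length_um Length in µm.
#' @param geometry A [voxel_geometry()].
#' @param axis `"xy"` or `"z"`.
#' @return Integer voxel count (>= 0).
#' @export
length_to_voxels <- function(length_um, geometry, axis = c("xy", "z")) {
  axis <- match.arg(axis)
  step <- if (axis == "xy") geometry$pixel_size_xy else geometry$z_step
  as.integer(floor(length_um / step + 0.5))
}

#' Per-axis voxel spacing as (y, x, z), in µm
#' @param geometry A [voxel_geometry()].
#' @return Numeric length-3 vector of spacings in µm.
#' @export
voxel_spacing <- function(geometry) {
  c(geometry$pixel_size_xy, geometry$pixel_size_xy, geometry$z_step)
}

#' Physical volume of one voxel in µm³
#' @param geometry A [voxel_geometry()].
#' @return Scalar volume in µm³.
#' @export
voxel_volume <- function(geometry) {
  geometry$pixel_size_xy^2 * geometry$z_step
}

# voxel-centre physical coordinates (µm) for 1-based voxel indices
voxel_centre_um <- function(y, x, z, geometry) {
  cbind(x = (x - 0.5) * geometry$pixel_size_xy,
        y = (y - 0.5) * geometry$pixel_size_xy,
        z = (z - 0.5) * geometry$z_step)
}

# physical position (µm) -> 1-based voxel index, clamped to the grid
um_to_voxel_index <- function(pos_um, dim3, geometry) {
  sp <- c(geometry$pixel_size_xy, geometry$pixel_size_xy, geometry$z_step)
  # pos_um columns x, y, z; grid dim is (ny, nx, nz)
  ix <- pmin(pmax(ceiling(pos_um[, 1] / sp[1]), 1L), dim3[2])
  iy <- pmin(pmax(ceiling(pos_um[, 2] / sp[2]), 1L), dim3[1])
  iz <- pmin(pmax(ceiling(pos_um[, 3] / sp[3]), 1L), dim3[3])
  cbind(y = iy, x = ix, z = iz)
}
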