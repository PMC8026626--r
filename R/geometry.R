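#' Voxel geometry of an OCT volume
#'
#' Physical geometry of a raster-scanned OCT volume indexed
#' `(b_scan, a_scan, depth)`: the first index runs along the slow scan axis,
#' the second along the fast axis, and the third from the vitreous toward the
#' choroid.  All depths are carried in micrometres from the top (vitreous
#' side) of the volume; lateral positions in millimetres relative to the
#' fovea.
#'
#' @param lateral_spacing_um numeric length-2, spacing along the
#'   `(slow, fast)` lateral axes in micrometres per A-scan.
#' @param axial_spacing_um axial sampling in micrometres per voxel.
#' @param dims integer length-3 `(n_bscan, n_ascan, n_depth)`.
#' @param fovea_index integer length-2 `(b_scan, a_scan)` of the foveal
#'   centre; defaults to the grid centre, matching fovea-centred acquisition.
#' @return An object of class `voxel_geometry`.
#' @export
voxel_geometry <- function(lateral_spacing_um, axial_spacing_um, dims,
                           fovea_index = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims > 0L),
            length(lateral_spacing_um) == 2L, all(lateral_spacing_um > 0),
            length(axial_spacing_um) == 1L, axial_spacing_um > 0)
  if (is.null(fovea_index)) {
    fovea_index <- c(dims[1L] %/% 2L + 1L, dims[2L] %/% 2L + 1L)
  }
  fovea_index <- as.integer(fovea_index)
  if (any(fovea_index < 1L) || fovea_index[1L] > dims[1L] ||
      fovea_index[2L] > dims[2L]) {
    stop("fovea_index must lie inside the lateral grid")
  }
  structure(
    list(lateral_spacing_um = as.numeric(lateral_spacing_um),
         axial_spacing_um = as.numeric(axial_spacing_um),
         dims = dims,
         fovea_index = fovea_index),
    class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf(
    "<voxel_geometry> %d x %d A-scans x %d depths; %.1f x %.1f um lateral, %.1f um axial; fovea at (%d, %d)\n",
    x$dims[1L], x$dims[2L], x$dims[3L],
    x$lateral_spacing_um[1L], x$lateral_spacing_um[2L], x$axial_spacing_um,
    x$fovea_index[1L], x$fovea_index[2L]))
  invisible(x)
}

#' Convert a physical depth to a voxel depth index
#'
#' Voxel `z` spans `[(z-1), z) * axial_spacing_um` with centre
#' `(z - 0.5) * axial_spacing_um`.  Conversion takes the index whose centre
#' is nearest to the requested depth; a depth exactly between two voxel
#' centres resolves toward the vitreous (smaller index).  The result is
#' clamped to the axial range.
#'
#' @param depth_um depth(s) in micrometres from the top of the volume.
#' @param geometry a [voxel_geometry()].
#' @return integer voxel index (1-based).
#' @export
depth_to_index <- function(depth_um, geometry) {
  idx <- ceiling(depth_um / geometry$axial_spacing_um)
  pmin(pmax(as.integer(idx), 1L), geometry$dims[3L])
}

#' Physical depth of a voxel centre
#'
#' Inverse of [depth_to_index()] on grid points.
#'
#' @inheritParams depth_to_index
#' @param index 1-based voxel depth index.
#' @return depth of the voxel centre in micrometres.
#' @export
index_to_depth <- function(index, geometry) {
  (index - 0.5) * geometry$axial_spacing_um
}

#' Lateral position maps relative to the fovea
#'
#' @inheritParams depth_to_index
#' @return list with matrices `x_mm` (fast axis), `y_mm` (slow axis) and
#'   `r_mm` (Euclidean distance from the fovea), each `n_bscan x n_ascan`.
#' @export
lateral_positions <- function(geometry) {
  nb <- geometry$dims[1L]; na_ <- geometry$dims[2L]
  y <- (seq_len(nb) - geometry$fovea_index[1L]) *
    geometry$lateral_spacing_um[1L] / 1000
  x <- (seq_len(na_) - geometry$fovea_index[2L]) *
    geometry$lateral_spacing_um[2L] / 1000
  x_mm <- matrix(x, nb, na_, byrow = TRUE)
  y_mm <- matrix(y, nb, na_)
  list(x_mm = x_mm, y_mm = y_mm, r_mm = sqrt(x_mm^2 + y_mm^2))
}
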