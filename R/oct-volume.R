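#' OCT volume container
#'
#' A 3D reflectivity volume with its physical geometry.  Intensities are kept
#' as floating point in `[0, 1]`; file storage quantizes to 16 bit (see
#' [write_volume()]).
#'
#' @param intensity 3D numeric array indexed `(b_scan, a_scan, depth)` with
#'   finite values in `[0, 1]` (`NA` marks voxels shifted out of range by
#'   flattening).
#' @param geometry a [voxel_geometry()] whose `dims` match `dim(intensity)`.
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(intensity, geometry) {
  stopifnot(is.array(intensity), length(dim(intensity)) == 3L,
            inherits(geometry, "voxel_geometry"))
  if (!all(dim(intensity) == geometry$dims)) {
    stop("intensity dimensions do not match geometry$dims")
  }
  rng <- if (anyNA(intensity)) range(intensity, na.rm = TRUE)
         else range(intensity)
  if (!all(is.finite(rng)) || rng[1L] < 0 || rng[2L] > 1) {
    stop("intensity must be finite and within [0, 1]")
  }
  structure(list(intensity = intensity, geometry = geometry),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  cat("<oct_volume>\n")
  print(x$geometry)
  invisible(x)
}

#' Named boundary-surface depth maps
#'
#' Per-A-scan depths (micrometres from the volume top) of retinal boundary
#' surfaces.  At least the inner limiting membrane (`ilm`), the inner
#' plexiform/inner nuclear boundary (`ipl_inl`), the ellipsoid zone (`ez`)
#' and the retinal pigment epithelium (`rpe`) must be present and ordered
#' `ilm < ipl_inl < ez < rpe` at every A-scan.  Additional surfaces (e.g.
#' `elm`) may be carried along.
#'
#' @param ... named `n_bscan x n_ascan` numeric matrices of depths in
#'   micrometres, or a single named list of such matrices.
#' @param axial_extent_um optional axial extent used to check that all
#'   surfaces lie inside the volume.
#' @return An object of class `surface_set` (a named list of matrices).
#' @export
surface_set <- function(..., axial_extent_um = NULL) {
  maps <- list(...)
  if (length(maps) == 1L && is.list(maps[[1L]]) && !is.matrix(maps[[1L]])) {
    maps <- maps[[1L]]
  }
  required <- c("ilm", "ipl_inl", "ez", "rpe")
  if (!all(required %in% names(maps))) {
    stop("surface_set requires maps named: ", paste(required, collapse = ", "))
  }
  d <- dim(maps[[1L]])
  for (nm in names(maps)) {
    if (!is.matrix(maps[[nm]]) || !all(dim(maps[[nm]]) == d)) {
      stop("all surface maps must be matrices of identical dimension")
    }
    if (anyNA(maps[[nm]]) || any(!is.finite(maps[[nm]]))) {
      stop("surface map '", nm, "' contains non-finite values")
    }
  }
  ord <- maps$ilm < maps$ipl_inl & maps$ipl_inl < maps$ez & maps$ez < maps$rpe
  if (!all(ord)) {
    stop("surface ordering ilm < ipl_inl < ez < rpe violated at ",
         sum(!ord), " A-scan(s)")
  }
  if (!is.null(axial_extent_um) &&
      (any(maps$ilm < 0) || any(maps$rpe > axial_extent_um))) {
    stop("surfaces fall outside the axial extent of the volume")
  }
  structure(maps, class = "surface_set")
}

#' @export
print.surface_set <- function(x, ...) {
  cat(sprintf("<surface_set> %s; %d x %d A-scans\n",
              paste(names(x), collapse = ", "), nrow(x[[1L]]), ncol(x[[1L]])))
  invisible(x)
}

#' En face image container
#'
#' @param pixels 2D numeric matrix `(n_bscan x n_ascan)`; `NA` marks pixels
#'   with no in-range voxels.
#' @param geometry the [voxel_geometry()] of the source volume.
#' @param slab the [slab_spec()] the image was projected from.
#' @return An object of class `enface_image`.
#' @export
enface_image <- function(pixels, geometry, slab) {
  stopifnot(is.matrix(pixels), inherits(geometry, "voxel_geometry"))
  if (!all(dim(pixels) == geometry$dims[1:2])) {
    stop("pixel dimensions must equal the lateral grid of the source volume")
  }
  structure(list(pixels = pixels, geometry = geometry, slab = slab),
            class = "enface_image")
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("<enface_image> %d x %d px; slab %s%+g um, depth %g um (%s)\n",
              nrow(x$pixels), ncol(x$pixels), x$slab$reference_surface,
              x$slab$offset_um, x$slab$depth_um, x$slab$projection))
  invisible(x)
}

# internal: volume array <-> (A-scan x depth) matrix view.  Index
# (b, a, z) maps to row b + (a - 1) * nb, so surface maps flatten with
# as.vector() in the same order.
vol_as_matrix <- function(intensity) {
  d <- dim(intensity)
  dim(intensity) <- c(d[1L] * d[2L], d[3L])
  intensity
}

matrix_as_vol <- function(m, dims) {
  dim(m) <- dims
  m
}
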