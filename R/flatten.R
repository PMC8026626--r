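#' Specify an en face slab
#'
#' A slab is an axial window tied to a named reference surface: it spans
#' `[reference + offset_um, reference + offset_um + depth_um)`.  Negative
#' offsets move toward the vitreous.  `depth_um = 0` selects the single
#' voxel plane nearest the reference.
#'
#' @param reference_surface name of a surface in the [surface_set()] used
#'   for flattening (e.g. `"ipl_inl"`, `"rpe"`, `"ilm"`).
#' @param offset_um signed offset from the reference surface in
#'   micrometres.
#' @param depth_um slab thickness in micrometres (>= 0).
#' @param projection `"mean"` (default), `"min"` or `"max"`.
#' @return An object of class `slab_spec`.
#' @export
slab_spec <- function(reference_surface, offset_um = 0, depth_um = 0,
                      projection = c("mean", "min", "max")) {
  projection <- match.arg(projection)
  if (depth_um < 0) stop("depth_um must be >= 0")
  structure(list(reference_surface = reference_surface,
                 offset_um = offset_um, depth_um = depth_um,
                 projection = projection),
            class = "slab_spec")
}

#' The standard slabs of the edema classification
#'
#' * `surface`: the retinal surface plane (ILM reference, scan depth 0),
#'   used for epiretinal membrane and retinal folds;
#' * `segment1`: IPL/INL reference, 50 um scan depth — the INL and OPL
#'   including Henle's fiber layer (the 50 um depth slightly exceeds the
#'   33--40 um INL so the OPL is included);
#' * `segment2`: RPE reference moved 70 um toward the vitreous as the
#'   inferior boundary (the RPE-to-ELM distance being 60--80 um), scan
#'   depth 50 um upward from there — the ONL;
#' * `subretinal`: the 70 um band directly above the RPE, used to decide
#'   the presence of subretinal fluid volumetrically.
#'
#' @return named list of [slab_spec()] objects.
#' @export
standard_slabs <- function() {
  list(surface = slab_spec("ilm", 0, 0),
       segment1 = slab_spec("ipl_inl", 0, 50),
       segment2 = slab_spec("rpe", -120, 50),
       subretinal = slab_spec("rpe", -70, 70))
}

#' Flatten a volume along a reference surface
#'
#' Shifts every A-scan axially so the chosen reference surface sits at a
#' constant depth row.  Voxels shifted out of the axial range become `NA`
#' and are excluded from slab projections.
#'
#' @param volume an [oct_volume()].
#' @param surfaces a [surface_set()] for the volume.
#' @param reference name of the surface to flatten along.
#' @return An object of class `flattened_volume`: fields `intensity`
#'   (array with `NA` padding), `geometry`, `reference_surface`,
#'   `reference_row` (constant depth row of the reference) and `surfaces`
#'   (all maps shifted into the flattened frame).
#' @export
flatten <- function(volume, surfaces, reference) {
  stopifnot(inherits(volume, "oct_volume"), inherits(surfaces, "surface_set"))
  if (!reference %in% names(surfaces)) {
    stop("reference surface '", reference, "' not present in surfaces")
  }
  ref_map <- surfaces[[reference]]
  if (anyNA(ref_map) || any(!is.finite(ref_map))) {
    stop("reference surface map contains non-finite values")
  }
  geom <- volume$geometry
  nz <- geom$dims[3L]
  ref_idx <- matrix(depth_to_index(ref_map, geom), nrow(ref_map))
  target <- as.integer(round(stats::median(ref_idx)))
  delta <- as.vector(target - ref_idx)     # +ve shifts toward the choroid

  M <- vol_as_matrix(volume$intensity)
  out <- matrix(NA_real_, nrow(M), nz)
  for (d in unique(delta)) {
    rows <- which(delta == d)
    if (d == 0L) {
      out[rows, ] <- M[rows, ]
    } else if (d > 0L) {
      out[rows, (d + 1L):nz] <- M[rows, 1L:(nz - d), drop = FALSE]
    } else {
      out[rows, 1L:(nz + d)] <- M[rows, (1L - d):nz, drop = FALSE]
    }
  }
  shift_um <- matrix(delta * geom$axial_spacing_um, nrow(ref_map))
  shifted <- lapply(unclass(surfaces), function(m) m + shift_um)
  structure(
    list(intensity = matrix_as_vol(out, geom$dims), geometry = geom,
         reference_surface = reference, reference_row = target,
         surfaces = structure(shifted, class = "surface_set")),
    class = "flattened_volume")
}

#' @export
print.flattened_volume <- function(x, ...) {
  cat(sprintf("<flattened_volume> reference %s at row %d\n",
              x$reference_surface, x$reference_row))
  print(x$geometry)
  invisible(x)
}

# depth rows sampled by a slab in a flattened volume
slab_rows <- function(flattened, slab) {
  geom <- flattened$geometry
  sp <- geom$axial_spacing_um
  r0 <- as.integer(ceiling(flattened$reference_row - 0.5 +
                             slab$offset_um / sp))
  n <- max(1L, as.integer(round(slab$depth_um / sp)))
  r0:(r0 + n - 1L)
}

#' Project a slab of a flattened volume to an en face image
#'
#' Each en face pixel is the projection (mean, min or max) of the voxel
#' intensities in `[reference + offset, reference + offset + depth)` along
#' that A-scan; `depth_um = 0` samples the single plane nearest the
#' reference.  Voxels marked missing by flattening are excluded; a pixel
#' with no in-range voxels is `NA`.
#'
#' @param flattened a [flattened_volume()] whose reference surface matches
#'   `slab$reference_surface`.
#' @param slab a [slab_spec()].
#' @return An [enface_image()].
#' @export
make_enface <- function(flattened, slab) {
  stopifnot(inherits(flattened, "flattened_volume"),
            inherits(slab, "slab_spec"))
  if (!identical(slab$reference_surface, flattened$reference_surface)) {
    stop("volume is flattened along '", flattened$reference_surface,
         "' but the slab references '", slab$reference_surface, "'")
  }
  geom <- flattened$geometry
  nz <- geom$dims[3L]
  rows <- slab_rows(flattened, slab)
  inside <- rows >= 1L & rows <= nz
  if (!any(inside)) stop("slab lies fully outside the axial extent")
  rows <- rows[inside]
  M <- vol_as_matrix(flattened$intensity)[, rows, drop = FALSE]
  px <- switch(slab$projection,
               mean = rowMeans(M, na.rm = TRUE),
               min = suppressWarnings(apply(M, 1L, min, na.rm = TRUE)),
               max = suppressWarnings(apply(M, 1L, max, na.rm = TRUE)))
  px[!is.finite(px)] <- NA_real_
  enface_image(matrix(px, geom$dims[1L], geom$dims[2L]), geom, slab)
}
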