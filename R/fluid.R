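#' Detect well-demarcated low-intensity fluid regions on an en face image
#'
#' Fluid appears on en face slabs as well-demarcated regions far darker
#' than any retinal tissue band.  The detector thresholds the image
#' (default: half the slab median, a scale-free rule; Otsu available),
#' closes small gaps morphologically, labels connected components and
#' discards those below a minimum area (speckle suppression; the default
#' 0.01 mm^2 corresponds to a ~110 um diameter spot).
#'
#' @param image an [enface_image()]; missing pixels are treated as median
#'   background.
#' @param threshold_mode `"fraction_of_median"` (default) or `"otsu"`.
#' @param fraction multiplier of the slab median when
#'   `threshold_mode = "fraction_of_median"` (default 0.5).
#' @param min_area_mm2 smallest retained component (default 0.01).
#' @param closing_radius_px radius of the morphological closing brush in
#'   pixels (default 1; 0 disables).
#' @return An object of class `fluid_mask`: `mask` (logical matrix),
#'   `regions` (data frame: `label`, `area_mm2`, `centroid_x_mm`,
#'   `centroid_y_mm` relative to the fovea), `source_slab`, `geometry`.
#' @export
detect_fluid <- function(image,
                         threshold_mode = c("fraction_of_median", "otsu"),
                         fraction = 0.5, min_area_mm2 = 0.01,
                         closing_radius_px = 1L) {
  stopifnot(inherits(image, "enface_image"))
  threshold_mode <- match.arg(threshold_mode)
  px <- image$pixels
  if (all(is.na(px))) stop("en face image is empty (all pixels missing)")
  med <- stats::median(px, na.rm = TRUE)
  px[is.na(px)] <- med
  thr <- switch(threshold_mode,
                fraction_of_median = fraction * med,
                otsu = EBImage::otsu(EBImage::Image(px)))
  mask <- px < thr
  if (any(mask) && closing_radius_px > 0L) {
    brush <- EBImage::makeBrush(2L * closing_radius_px + 1L, shape = "disc")
    mask <- EBImage::closing(mask * 1, brush) > 0.5
  }
  geom <- image$geometry
  px_area <- prod(geom$lateral_spacing_um) / 1e6  # mm^2 per pixel
  lab <- EBImage::bwlabel(mask * 1)
  nlab <- max(lab)
  regions <- data.frame(label = integer(0), area_mm2 = numeric(0),
                        centroid_x_mm = numeric(0), centroid_y_mm = numeric(0))
  if (nlab > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = nlab) * px_area
    keep <- which(areas >= min_area_mm2)
    if (length(keep) > 0L) {
      pos <- lateral_positions(geom)
      cx <- vapply(keep, function(k) mean(pos$x_mm[lab == k]), numeric(1))
      cy <- vapply(keep, function(k) mean(pos$y_mm[lab == k]), numeric(1))
      regions <- data.frame(label = seq_along(keep), area_mm2 = areas[keep],
                            centroid_x_mm = cx, centroid_y_mm = cy)
    }
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  structure(list(mask = mask, regions = regions,
                 source_slab = image$slab$reference_surface,
                 slab = image$slab, geometry = geom),
            class = "fluid_mask")
}

#' @export
print.fluid_mask <- function(x, ...) {
  cat(sprintf("<fluid_mask> %d region(s), total %.3f mm^2\n",
              nrow(x$regions), sum(x$regions$area_mm2)))
  invisible(x)
}

#' Detect subretinal fluid in the subretinal slab
#'
#' Subretinal fluid is decided volumetrically: the 70 um band directly
#' above the RPE is normally filled by the hyperreflective photoreceptor
#' bands, so any sufficiently large low-intensity component there is
#' subretinal fluid.  (On the ONL slab the same fluid produces the
#' characteristic high-intensity ring, which is an appearance rather than
#' a rule.)
#'
#' @param subretinal_image an [enface_image()] built from the
#'   `subretinal` slab of [standard_slabs()].
#' @param min_area_mm2 smallest component counted as subretinal fluid
#'   (default 0.05).
#' @param ... further arguments passed to [detect_fluid()].
#' @return a `fluid_mask` with an extra element `present` (logical).
#' @export
detect_srf <- function(subretinal_image, min_area_mm2 = 0.05, ...) {
  fm <- detect_fluid(subretinal_image, min_area_mm2 = min_area_mm2, ...)
  fm$present <- nrow(fm$regions) > 0L
  fm
}
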