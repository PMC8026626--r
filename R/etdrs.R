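#' ETDRS grid centred at the fovea
#'
#' The foveal circle has a 1 mm diameter and the parafoveal circle a 3 mm
#' diameter; the radii are fixed by definition.
#'
#' @return An object of class `etdrs_grid` with `foveal_radius_mm = 0.5`
#'   and `parafoveal_radius_mm = 1.5`.
#' @export
etdrs_grid <- function() {
  structure(list(foveal_radius_mm = 0.5, parafoveal_radius_mm = 1.5),
            class = "etdrs_grid")
}

#' Classify the lateral extent of detected fluid against the ETDRS zones
#'
#' * `NF`: no fluid;
#' * `FC` (foveal cystoid space): every fluid pixel centre lies within the
#'   0.5 mm foveal circle;
#' * `PC` (parafoveal cystoid space): fluid extends beyond the foveal
#'   circle but stays within the 1.5 mm parafoveal circle;
#' * `DF` (diffuse fluid): fluid extends beyond the parafoveal circle.
#'
#' Containment is evaluated at pixel centres against the exact circle
#' radii, which makes the rule resolution independent.  `tolerance_px`
#' out-of-zone pixels may be ignored (default 0: the rule is absolute).
#'
#' @param fluid a `fluid_mask` from [detect_fluid()].
#' @param grid an [etdrs_grid()].
#' @param tolerance_px number of out-of-zone pixels to ignore.
#' @return one of `"NF"`, `"FC"`, `"PC"`, `"DF"`.
#' @export
classify_extent <- function(fluid, grid = etdrs_grid(), tolerance_px = 0L) {
  stopifnot(inherits(fluid, "fluid_mask"), inherits(grid, "etdrs_grid"))
  if (!any(fluid$mask)) return("NF")
  pos <- lateral_positions(fluid$geometry)
  r <- pos$r_mm[fluid$mask]
  if (sum(r > grid$foveal_radius_mm) <= tolerance_px) return("FC")
  if (sum(r > grid$parafoveal_radius_mm) <= tolerance_px) return("PC")
  "DF"
}

#' Enumerate the edema taxonomy
#'
#' Crossing the four Segment-1 states (NF, FC, PC, DF) with the four
#' Segment-2 states (NF, DF, SF alone, DF + SF) gives 16 combinations; the
#' all-no-fluid combination is not edema, leaving 15 labels.  Only five are
#' observed in practice ([observed_types()]).
#'
#' @return character vector of the 15 combination labels.
#' @export
taxonomy_labels <- function() {
  s1 <- c("NF", "FC", "PC", "DF")
  s2 <- c("NF", "DF", "SF", "DF + SF")
  labels <- as.vector(outer(s1, s2, function(a, b) paste0(a, "/", b)))
  setdiff(labels, "NF/NF")
}

#' Combine per-segment findings into an edema classification
#'
#' @param segment1_state one of `"NF"`, `"FC"`, `"PC"`, `"DF"`.
#' @param segment2_state `"NF"` or `"DF"` (Segment 2 is evaluated for
#'   presence only).
#' @param srf_present logical, subretinal fluid present.
#' @return An object of class `dme_classification`: `label` (one of the 15
#'   taxonomy labels, or `"none"` when no fluid is found anywhere — the
#'   not-DME signal), `observed_type` (the label when it is one of the five
#'   observed types, otherwise `NA`), the input states and `is_dme`.
#' @export
combine_segments <- function(segment1_state, segment2_state, srf_present) {
  stopifnot(segment1_state %in% c("NF", "FC", "PC", "DF"),
            segment2_state %in% c("NF", "DF"),
            is.logical(srf_present), length(srf_present) == 1L)
  if (segment1_state == "NF" && segment2_state == "NF" && !srf_present) {
    cls <- list(label = "none", observed_type = NA_character_,
                segment1_state = "NF", segment2_state = "NF",
                srf_present = FALSE, is_dme = FALSE)
    return(structure(cls, class = "dme_classification"))
  }
  s2_label <- if (segment2_state == "DF") {
    if (srf_present) "DF + SF" else "DF"
  } else {
    if (srf_present) "SF" else "NF"
  }
  label <- paste0(segment1_state, "/", s2_label)
  stopifnot(label %in% taxonomy_labels())
  structure(
    list(label = label,
         observed_type = if (label %in% observed_types()) label
                         else NA_character_,
         segment1_state = segment1_state, segment2_state = segment2_state,
         srf_present = srf_present, is_dme = TRUE),
    class = "dme_classification")
}

#' @export
print.dme_classification <- function(x, ...) {
  if (!x$is_dme) {
    cat("<dme_classification> no fluid detected (not DME)\n")
  } else {
    cat(sprintf("<dme_classification> %s%s\n", x$label,
                if (is.na(x$observed_type)) " (unobserved combination)" else ""))
  }
  invisible(x)
}

#' Classify an eye end to end from its OCT volume
#'
#' Runs the full pipeline: surface segmentation (unless ground-truth
#' surfaces are supplied), flattening along the IPL/INL and RPE, standard
#' slab projection, fluid detection on Segments 1 and 2, volumetric
#' subretinal fluid detection, ETDRS extent classification and taxonomy
#' combination.  Segment 2 is reduced to fluid presence/absence; its
#' measured extent is still recorded in the provenance.
#'
#' @param volume an [oct_volume()].
#' @param surfaces optional [surface_set()]; defaults to
#'   [segment_surfaces()] output.
#' @param grid an [etdrs_grid()].
#' @param fluid_params list of arguments passed to [detect_fluid()].
#' @param srf_params list of arguments passed to [detect_srf()].
#' @return list with `classification` (a `dme_classification`), `fluid`
#'   (the Segment-1/Segment-2/subretinal `fluid_mask`s) and `provenance`
#'   (slab definitions, detector parameters, per-segment states, areas and
#'   the measured Segment-2 extent).
#' @export
classify_eye <- function(volume, surfaces = NULL, grid = etdrs_grid(),
                         fluid_params = list(), srf_params = list()) {
  stopifnot(inherits(volume, "oct_volume"))
  if (is.null(surfaces)) surfaces <- segment_surfaces(volume)
  slabs <- standard_slabs()

  flat_inl <- flatten(volume, surfaces, "ipl_inl")
  img1 <- make_enface(flat_inl, slabs$segment1)
  flat_rpe <- flatten(volume, surfaces, "rpe")
  img2 <- make_enface(flat_rpe, slabs$segment2)
  img_sub <- make_enface(flat_rpe, slabs$subretinal)

  f1 <- do.call(detect_fluid, c(list(img1), fluid_params))
  f2 <- do.call(detect_fluid, c(list(img2), fluid_params))
  srf <- do.call(detect_srf, c(list(img_sub), srf_params))

  s1 <- classify_extent(f1, grid)
  s2_extent <- classify_extent(f2, grid)
  s2 <- if (s2_extent == "NF") "NF" else "DF"
  cls <- combine_segments(s1, s2, srf$present)

  provenance <- list(
    slabs = slabs,
    fluid_params = fluid_params, srf_params = srf_params,
    segment1_state = s1, segment2_state = s2,
    segment2_measured_extent = s2_extent,
    segment1_area_mm2 = sum(f1$regions$area_mm2),
    segment2_area_mm2 = sum(f2$regions$area_mm2),
    srf_area_mm2 = sum(srf$regions$area_mm2),
    surfaces_estimated = is.null(attr(surfaces, "ground_truth")),
    n_interpolated_surfaces = attr(surfaces, "n_interpolated"))
  list(classification = cls,
       fluid = list(segment1 = f1, segment2 = f2, subretinal = srf),
       provenance = provenance)
}
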