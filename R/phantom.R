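#' Describe a fluid pocket for the phantom generator
#'
#' Pockets live strictly inside a named retinal band: Henle pockets occupy
#' the OPL/Henle band, INL pockets the inner nuclear layer, ONL pockets the
#' outer nuclear layer, and subretinal pockets lift the neurosensory retina
#' off the RPE.  `cystoid_cluster` pockets are rendered as steep-walled
#' cylinders (cystoid spaces), `diffuse_sheet` pockets fill the whole band
#' over a lateral disk.
#'
#' @param layer one of `"Henle"`, `"INL"`, `"ONL"`, `"subretinal"`.
#' @param shape `"cystoid_cluster"` or `"diffuse_sheet"` (ignored for
#'   subretinal pockets, which are always blister-shaped).
#' @param center_mm lateral centre `(x, y)` in millimetres from the fovea.
#' @param radius_mm lateral radius in millimetres (> 0).
#' @param height_um axial height in micrometres; `NULL` fills the band
#'   (for subretinal pockets: blister height).
#' @return An object of class `fluid_pocket`.
#' @export
fluid_pocket <- function(layer = c("Henle", "INL", "ONL", "subretinal"),
                         shape = c("cystoid_cluster", "diffuse_sheet"),
                         center_mm = c(0, 0), radius_mm, height_um = NULL) {
  layer <- match.arg(layer)
  shape <- match.arg(shape)
  if (!is.numeric(radius_mm) || radius_mm <= 0) {
    stop("fluid pocket radius_mm must be > 0")
  }
  if (!is.null(height_um) && height_um <= 0) stop("height_um must be > 0")
  structure(list(layer = layer, shape = shape,
                 center_mm = as.numeric(center_mm),
                 radius_mm = radius_mm, height_um = height_um),
            class = "fluid_pocket")
}

#' Specify a synthetic macular OCT phantom
#'
#' Defines the geometry, layered anatomy, fluid configuration and noise of a
#' synthetic macular volume.  Band thickness defaults place the external
#' limiting membrane 70 um above the RPE (the reported RPE-to-ELM distance
#' is 60--80 um) and make the INL 35 um thick (reported 33--40 um), so the
#' standard en face slabs sample the intended bands.
#'
#' @param lateral_extent_mm scanned area, default `c(6, 6)` mm.
#' @param n_ascans lateral grid `(n_bscan, n_ascan)`; default `c(128, 128)`
#'   (use `c(256, 512)` to match a 512 x 256 line acquisition).
#' @param axial_spacing_um axial sampling, default 5 um/voxel.
#' @param axial_extent_um axial field depth, default 1500 um.
#' @param rpe_depth_um depth of the (flat) RPE inner surface, default 900 um.
#' @param layer_thicknesses_um named list with elements `inner` (ILM to
#'   IPL/INL), `inl`, `opl_henle`, `onl`, `elm_rpe` and `elm_ez` (ELM to the
#'   ellipsoid-zone centre); see defaults.
#' @param foveal_pit list `inner_frac`, `inl_frac` (fractional thinning of
#'   the inner retina and INL at the foveal centre) and `sigma_mm` (Gaussian
#'   radius of the pit).
#' @param fluid_config list of [fluid_pocket()] objects.
#' @param erm_config `NULL`, or list with `fold_depth_um` (depth below the
#'   ILM at which traction folds vanish; this is the ground-truth MDRF),
#'   `fold_spacing_um`, `fold_width_um`, `coverage` (areal fraction of the
#'   adherent hyperreflective membrane), `membrane_um` (membrane thickness).
#' @param ez_gap_config `NULL`, or list `center_mm`, `radius_mm` of a disk
#'   where the ellipsoid-zone band is erased.
#' @param srf_config `NULL`, or list `center_mm`, `radius_mm`, `height_um`
#'   of a subretinal fluid blister (equivalent to a subretinal pocket).
#' @param pvd_label `"complete"`, `"incomplete"` or `"attached"`; carried as
#'   a ground-truth label only.
#' @param noise list `amplitude` (multiplicative speckle amplitude; 0
#'   disables) and `seed`.
#' @param intensity_map named mean reflectivities in `[0, 1]`; see defaults.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(lateral_extent_mm = c(6, 6),
                         n_ascans = c(128, 128),
                         axial_spacing_um = 5,
                         axial_extent_um = 1500,
                         rpe_depth_um = 900,
                         layer_thicknesses_um = list(
                           inner = 100, inl = 35, opl_henle = 35,
                           onl = 70, elm_rpe = 70, elm_ez = 25),
                         foveal_pit = list(inner_frac = 0.9, inl_frac = 0.85,
                                           sigma_mm = 0.35),
                         fluid_config = list(),
                         erm_config = NULL,
                         ez_gap_config = NULL,
                         srf_config = NULL,
                         pvd_label = c("complete", "incomplete", "attached"),
                         noise = list(amplitude = 0.15, seed = 1L),
                         intensity_map = list(
                           vitreous = 0.02, inner = 0.50, nuclear = 0.25,
                           plexiform = 0.55, photoreceptor = 0.40,
                           ez = 0.90, rpe = 0.90, choroid = 0.15,
                           fluid = 0.05, membrane = 0.85, fold = 0.15)) {
  pvd_label <- match.arg(pvd_label)
  th <- layer_thicknesses_um
  stopifnot(all(unlist(th) > 0), axial_spacing_um > 0, axial_extent_um > 0)
  retina <- th$inner + th$inl + th$opl_henle + th$onl + th$elm_rpe
  if (rpe_depth_um - retina < 0 ||
      rpe_depth_um + 30 > axial_extent_um) {
    stop("retina does not fit in the axial extent")
  }
  if (!is.null(erm_config)) {
    erm_config <- utils::modifyList(
      list(fold_depth_um = 50, fold_spacing_um = 600, fold_width_um = 50,
           coverage = 0.35, membrane_um = 12), erm_config)
  }
  if (!is.null(srf_config)) {
    srf_config <- utils::modifyList(
      list(center_mm = c(0, 0), radius_mm = 0.8, height_um = 80), srf_config)
  }
  if (!is.null(ez_gap_config)) {
    ez_gap_config <- utils::modifyList(
      list(center_mm = c(0, 0), radius_mm = 0.3), ez_gap_config)
  }
  noise <- utils::modifyList(list(amplitude = 0.15, seed = 1L), noise)
  for (p in fluid_config) {
    if (!inherits(p, "fluid_pocket")) {
      stop("fluid_config must be a list of fluid_pocket objects")
    }
  }
  structure(
    list(lateral_extent_mm = lateral_extent_mm, n_ascans = as.integer(n_ascans),
         axial_spacing_um = axial_spacing_um, axial_extent_um = axial_extent_um,
         rpe_depth_um = rpe_depth_um, layer_thicknesses_um = th,
         foveal_pit = foveal_pit, fluid_config = fluid_config,
         erm_config = erm_config, ez_gap_config = ez_gap_config,
         srf_config = srf_config, pvd_label = pvd_label, noise = noise,
         intensity_map = intensity_map),
    class = "phantom_spec")
}

# run code with a fixed seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# low-frequency random field in [0,1]-ish, bilinearly upsampled from a
# coarse grid; used for membrane patch placement
smooth_noise_field <- function(nb, na_, ngrid = 12L) {
  coarse <- matrix(stats::runif((ngrid + 1L)^2), ngrid + 1L, ngrid + 1L)
  gi <- seq(1, ngrid + 1L, length.out = nb)
  gj <- seq(1, ngrid + 1L, length.out = na_)
  i0 <- pmin(floor(gi), ngrid); j0 <- pmin(floor(gj), ngrid)
  fi <- gi - i0; fj <- gj - j0
  a <- coarse[cbind(rep(i0, length(j0)), rep(j0, each = length(i0)))]
  b <- coarse[cbind(rep(i0 + 1L, length(j0)), rep(j0, each = length(i0)))]
  c_ <- coarse[cbind(rep(i0, length(j0)), rep(j0 + 1L, each = length(i0)))]
  d <- coarse[cbind(rep(i0 + 1L, length(j0)), rep(j0 + 1L, each = length(i0)))]
  FI <- rep(fi, length(j0)); FJ <- rep(fj, each = length(i0))
  v <- a * (1 - FI) * (1 - FJ) + b * FI * (1 - FJ) +
    c_ * (1 - FI) * FJ + d * FI * FJ
  matrix(v, nb, na_)
}

band_for_layer <- function(layer, bands) {
  switch(layer,
         Henle = list(top = bands$inl_opl, bottom = bands$onl_top),
         INL = list(top = bands$ipl_inl, bottom = bands$inl_opl),
         ONL = list(top = bands$onl_top, bottom = bands$elm),
         stop("no axial band for layer '", layer, "'"))
}

#' Generate a synthetic macular OCT phantom with ground truth
#'
#' Renders the layered reflectivity volume described by a [phantom_spec()]
#' and returns it together with exact ground truth: boundary surfaces, 3D
#' fluid and subretinal-fluid masks, the edema type label implied by the
#' fluid configuration, and biomarker truth values.  Identical spec (and
#' seed) gives an identical volume.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` (an [oct_volume()]) and `truth`
#'   (class `phantom_truth`: `surfaces`, `fluid_mask`, `srf_mask`,
#'   `type_label`, `erm_present`, `mdrf_true_um`, `ez_disrupted`,
#'   `pvd_label`, `spec`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_local_seed(spec$noise$seed, {
    nb <- spec$n_ascans[1L]; na_ <- spec$n_ascans[2L]
    nz <- as.integer(round(spec$axial_extent_um / spec$axial_spacing_um))
    geom <- voxel_geometry(
      lateral_spacing_um = spec$lateral_extent_mm * 1000 / c(nb, na_),
      axial_spacing_um = spec$axial_spacing_um,
      dims = c(nb, na_, nz))
    pos <- lateral_positions(geom)
    x <- as.vector(pos$x_mm); y <- as.vector(pos$y_mm); r <- as.vector(pos$r_mm)
    nA <- nb * na_
    th <- spec$layer_thicknesses_um
    im <- spec$intensity_map

    pit <- exp(-r^2 / (2 * spec$foveal_pit$sigma_mm^2))
    rpe <- rep(spec$rpe_depth_um, nA)
    elm <- rpe - th$elm_rpe
    onl_top <- elm - th$onl
    inl_opl <- onl_top - th$opl_henle
    ipl_inl <- inl_opl - th$inl * (1 - spec$foveal_pit$inl_frac * pit)
    ilm <- ipl_inl - th$inner * (1 - spec$foveal_pit$inner_frac * pit)
    ez <- elm + th$elm_ez

    # subretinal blister height field: plateau with a cosine taper over the
    # outer 5% of the radius, so the painted lateral extent is well defined
    srf_list <- Filter(function(p) p$layer == "subretinal", spec$fluid_config)
    if (!is.null(spec$srf_config)) {
      s <- spec$srf_config
      srf_list <- c(srf_list, list(fluid_pocket(
        "subretinal", center_mm = s$center_mm, radius_mm = s$radius_mm,
        height_um = s$height_um)))
    }
    h <- numeric(nA)
    for (p in srf_list) {
      H <- if (is.null(p$height_um)) 80 else p$height_um
      rd <- sqrt((x - p$center_mm[1L])^2 + (y - p$center_mm[2L])^2) / p$radius_mm
      taper <- pmin(pmax((1 - rd) / 0.05, 0), 1)
      hp <- H * 0.5 * (1 - cos(pi * taper))
      h <- pmax(h, hp)
    }
    if (any(h > 0)) {
      shift <- h
      ilm <- ilm - shift; ipl_inl <- ipl_inl - shift
      inl_opl <- inl_opl - shift; onl_top <- onl_top - shift
      elm <- elm - shift; ez <- ez - shift
    }
    if (any(ilm < 2 * spec$axial_spacing_um)) {
      stop("retina shifted out of the axial extent; increase axial_extent_um")
    }

    bands <- list(ipl_inl = ipl_inl, inl_opl = inl_opl,
                  onl_top = onl_top, elm = elm)

    # adherent epiretinal membrane: truth ILM includes it where present
    erm <- spec$erm_config
    ilm_out <- ilm
    patch <- rep(FALSE, nA)
    line_mask <- rep(FALSE, nA)
    if (!is.null(erm)) {
      field <- smooth_noise_field(nb, na_)
      patch <- as.vector(field > stats::quantile(field, 1 - erm$coverage))
      ilm_out <- ilm - erm$membrane_um * patch
      phase <- (x * 1000) %% erm$fold_spacing_um
      line_mask <- phase < erm$fold_width_um & r > 0.9
    }

    # paint bands top-down; later assignments overwrite earlier ones
    zc <- index_to_depth(seq_len(nz), geom)
    Zc <- matrix(zc, nA, nz, byrow = TRUE)
    M <- matrix(im$vitreous, nA, nz)
    M[Zc >= ilm] <- im$inner
    M[Zc >= ipl_inl] <- im$nuclear
    M[Zc >= inl_opl] <- im$plexiform
    M[Zc >= onl_top] <- im$nuclear
    M[Zc >= elm] <- im$photoreceptor
    M[Zc >= ez - 10] <- im$ez
    M[Zc >= ez + 10] <- im$photoreceptor
    M[Zc >= rpe - h] <- im$fluid
    M[Zc >= rpe] <- im$rpe
    M[Zc >= rpe + 25] <- im$choroid

    srf_mask <- Zc >= rpe - h & Zc < rpe & h > 0

    if (!is.null(spec$ez_gap_config)) {
      g <- spec$ez_gap_config
      gd <- sqrt((x - g$center_mm[1L])^2 + (y - g$center_mm[2L])^2)
      gap <- gd <= g$radius_mm
      M[gap & Zc >= ez - 10 & Zc < ez + 10] <- im$nuclear
    }

    fluid_mask <- matrix(FALSE, nA, nz)
    for (p in spec$fluid_config) {
      if (p$layer == "subretinal") next  # rendered via the blister field
      bd <- band_for_layer(p$layer, bands)
      lat <- sqrt((x - p$center_mm[1L])^2 + (y - p$center_mm[2L])^2) <= p$radius_mm
      if (!any(lat)) {
        stop("fluid pocket at (", p$center_mm[1L], ", ", p$center_mm[2L],
             ") mm lies outside the scanned area")
      }
      if (p$shape == "diffuse_sheet" || is.null(p$height_um)) {
        top <- bd$top; bottom <- bd$bottom
      } else {
        band_th <- bd$bottom - bd$top
        if (p$height_um > max(band_th) + 1e-9) {
          stop("fluid pocket height ", p$height_um,
               " um exceeds the ", p$layer, " band thickness")
        }
        mid <- (bd$top + bd$bottom) / 2
        top <- pmax(mid - p$height_um / 2, bd$top)
        bottom <- pmin(mid + p$height_um / 2, bd$bottom)
      }
      pm <- lat & Zc >= top & Zc < bottom
      M[pm] <- im$fluid
      fluid_mask <- fluid_mask | pm
    }

    if (!is.null(erm)) {
      M[patch & Zc >= ilm_out & Zc < ilm] <- im$membrane
      M[line_mask & Zc >= ilm_out & Zc < ilm_out + erm$fold_depth_um] <- im$fold
    }

    if (spec$noise$amplitude > 0) {
      k <- 1 / spec$noise$amplitude^2
      M <- M * stats::rgamma(length(M), shape = k, rate = k)
      M <- pmin(pmax(M, 0), 1)
    }

    surfaces <- surface_set(
      list(ilm = matrix(ilm_out, nb, na_),
           ipl_inl = matrix(ipl_inl, nb, na_),
           ez = matrix(ez, nb, na_),
           rpe = matrix(rpe, nb, na_),
           elm = matrix(elm, nb, na_),
           inl_opl = matrix(inl_opl, nb, na_),
           onl_top = matrix(onl_top, nb, na_)),
      axial_extent_um = spec$axial_extent_um)

    truth <- structure(
      list(surfaces = surfaces,
           fluid_mask = matrix_as_vol(fluid_mask, c(nb, na_, nz)),
           srf_mask = matrix_as_vol(srf_mask, c(nb, na_, nz)),
           type_label = phantom_type_label(spec),
           erm_present = !is.null(erm),
           mdrf_true_um = if (is.null(erm)) NA_real_ else erm$fold_depth_um,
           ez_disrupted = phantom_ez_truth(spec),
           pvd_label = spec$pvd_label,
           spec = spec),
      class = "phantom_truth")
    list(volume = oct_volume(matrix_as_vol(M, c(nb, na_, nz)), geom),
         truth = truth)
  })
}

# type label implied by a fluid configuration (self-check against the
# classification taxonomy happens in combine_segments)
phantom_type_label <- function(spec) {
  pockets <- spec$fluid_config
  s1 <- Filter(function(p) p$layer %in% c("Henle", "INL"), pockets)
  s2 <- Filter(function(p) p$layer == "ONL", pockets)
  srf <- length(Filter(function(p) p$layer == "subretinal", pockets)) > 0 ||
    !is.null(spec$srf_config)
  s1_state <- if (length(s1) == 0L) "NF" else {
    ext <- max(vapply(s1, function(p)
      sqrt(sum(p$center_mm^2)) + p$radius_mm, numeric(1)))
    if (ext <= 0.5) "FC" else if (ext <= 1.5) "PC" else "DF"
  }
  s2_state <- if (length(s2) == 0L) "NF" else "DF"
  if (s1_state == "NF" && s2_state == "NF" && !srf) return("control")
  combine_segments(s1_state, s2_state, srf)$label
}

# ground-truth EZ disruption: does the erased EZ disk leave a chord of at
# least gap_min_um on the horizontal or vertical B-scan through the fovea,
# within +/- 1.5 mm of it?
phantom_ez_truth <- function(spec, gap_min_um = 50) {
  g <- spec$ez_gap_config
  if (is.null(g)) return(FALSE)
  chord_ok <- function(center_along, center_across, rad) {
    if (abs(center_across) >= rad) return(0)
    half <- sqrt(rad^2 - center_across^2)
    lo <- max(center_along - half, -1.5)
    hi <- min(center_along + half, 1.5)
    max(hi - lo, 0) * 1000
  }
  horiz <- chord_ok(g$center_mm[1L], g$center_mm[2L], g$radius_mm)
  vert <- chord_ok(g$center_mm[2L], g$center_mm[1L], g$radius_mm)
  max(horiz, vert) >= gap_min_um
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "<phantom_truth> type %s; ERM %s (MDRF %s um); EZ disrupted %s; PVD %s\n",
    x$type_label, x$erm_present,
    ifelse(is.na(x$mdrf_true_um), "-", format(x$mdrf_true_um)),
    x$ez_disrupted, x$pvd_label))
  invisible(x)
}
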