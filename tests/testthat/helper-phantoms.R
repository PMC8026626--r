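# small phantoms for unit tests: 64 x 64 A-scans over 6 x 6 mm, 900 um
# axial extent; acquisition-sized grids are exercised in the acceptance
# suite only
tiny_spec <- function(..., amplitude = 0, seed = 1L, n = 64L) {
  phantom_spec(n_ascans = c(n, n), axial_extent_um = 900, rpe_depth_um = 620,
               noise = list(amplitude = amplitude, seed = seed), ...)
}

fc_pocket <- function(radius_mm = 0.4) {
  list(fluid_pocket("Henle", "cystoid_cluster", c(0, 0), radius_mm))
}

df_pockets <- function() {
  list(fluid_pocket("Henle", "diffuse_sheet", c(0, 0), 1.9),
       fluid_pocket("INL", "diffuse_sheet", c(0, 0), 1.8),
       fluid_pocket("ONL", "diffuse_sheet", c(0, 0), 2.0))
}

# geometry + blank en face image for detector tests
toy_image <- function(pixels, spacing_um = c(93.75, 93.75),
                      slab = slab_spec("ipl_inl", 0, 50)) {
  geom <- voxel_geometry(lateral_spacing_um = spacing_um,
                         axial_spacing_um = 5,
                         dims = c(nrow(pixels), ncol(pixels), 8L))
  enface_image(pixels, geom, slab)
}

# disk mask of given radius (mm) centred at the fovea
disk_pixels <- function(n = 64L, radius_mm, value = 0.05, bg = 0.55,
                        spacing_um = 93.75, center_mm = c(0, 0)) {
  geom <- voxel_geometry(lateral_spacing_um = rep(spacing_um, 2L),
                         axial_spacing_um = 5, dims = c(n, n, 8L))
  pos <- lateral_positions(geom)
  px <- matrix(bg, n, n)
  px[sqrt((pos$x_mm - center_mm[1])^2 +
            (pos$y_mm - center_mm[2])^2) <= radius_mm] <- value
  px
}
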