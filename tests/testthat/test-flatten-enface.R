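flat_surfaces <- function(geom, ilm = 60, ipl = 120, ez = 240, rpe = 280) {
  nb <- geom$dims[1L]; na_ <- geom$dims[2L]
  surface_set(list(ilm = matrix(ilm, nb, na_), ipl_inl = matrix(ipl, nb, na_),
                   ez = matrix(ez, nb, na_), rpe = matrix(rpe, nb, na_)))
}

test_that("segmentation refuses a volume without boundaries", {
  geom <- voxel_geometry(c(50, 50), 5, c(8, 8, 40))
  v <- oct_volume(array(0.5, c(8, 8, 40)), geom)
  expect_error(segment_surfaces(v), "near-constant")
})

test_that("noise-free segmentation is within one voxel of truth", {
  for (fl in list(list(), fc_pocket(0.4), df_pockets())) {
    ph <- generate_phantom(tiny_spec(fluid_config = fl))
    ss <- segment_surfaces(ph$volume)
    for (nm in c("ilm", "ipl_inl", "ez", "rpe")) {
      expect_lte(max(abs(ss[[nm]] - ph$truth$surfaces[[nm]])),
                 ph$volume$geometry$axial_spacing_um)
    }
  }
})

test_that("under speckle the median surface error stays within two voxels", {
  ph <- generate_phantom(tiny_spec(fluid_config = fc_pocket(0.4),
                                   amplitude = 0.15, seed = 31))
  ss <- segment_surfaces(ph$volume)
  for (nm in c("ilm", "ipl_inl", "ez", "rpe")) {
    expect_lte(stats::median(abs(ss[[nm]] - ph$truth$surfaces[[nm]])),
               2 * ph$volume$geometry$axial_spacing_um)
  }
})

test_that("flattening pins the reference surface to a constant row", {
  ph <- generate_phantom(tiny_spec(fluid_config = fc_pocket(0.3)))
  ss <- ph$truth$surfaces
  fl <- flatten(ph$volume, ss, "rpe")
  idx <- depth_to_index(fl$surfaces$rpe, fl$geometry)
  expect_lte(max(abs(idx - fl$reference_row)), 1L)
  # idempotence: flattening the flattened volume changes nothing
  v2 <- oct_volume(ifelse(is.na(fl$intensity), 0, fl$intensity), fl$geometry)
  fl2 <- flatten(v2, fl$surfaces, "rpe")
  expect_lte(max(abs(fl2$intensity - fl$intensity), na.rm = TRUE), 0)
  # non-finite reference is rejected
  ss_bad <- ss; ss_bad$rpe[1, 1] <- NA
  expect_error(flatten(ph$volume, ss_bad, "rpe"), "non-finite")
  expect_error(flatten(ph$volume, ss, "bogus"), "not present")
})

test_that("projection of a constant volume is that constant", {
  geom <- voxel_geometry(c(50, 50), 5, c(10, 10, 60))
  v <- oct_volume(array(0.5, c(10, 10, 60)), geom)
  fl <- flatten(v, flat_surfaces(geom), "ipl_inl")
  for (slab in list(slab_spec("ipl_inl", 0, 50), slab_spec("ipl_inl", -30, 0),
                    slab_spec("ipl_inl", 20, 40, "max"))) {
    img <- make_enface(fl, slab)
    expect_true(all(img$pixels == 0.5))
  }
  expect_error(make_enface(fl, slab_spec("ipl_inl", 1e5, 10)), "outside")
  expect_error(make_enface(fl, slab_spec("rpe", 0, 10)), "flattened along")
})

test_that("en face projection matches a brute-force per-pixel loop exactly", {
  set.seed(99)
  geom <- voxel_geometry(c(375, 375), 5, c(16, 16, 64))
  v <- oct_volume(array(runif(16 * 16 * 64), c(16, 16, 64)), geom)
  fl <- flatten(v, flat_surfaces(geom, 80, 120, 200, 250), "rpe")
  for (slab in list(slab_spec("rpe", -120, 50), slab_spec("rpe", -70, 70),
                    slab_spec("rpe", 0, 0),
                    slab_spec("rpe", -50, 30, "min"),
                    slab_spec("rpe", -50, 30, "max"))) {
    img <- make_enface(fl, slab)
    sp <- geom$axial_spacing_um
    r0 <- ceiling(fl$reference_row - 0.5 + slab$offset_um / sp)
    n <- max(1, round(slab$depth_um / sp))
    rows <- (r0:(r0 + n - 1))
    rows <- rows[rows >= 1 & rows <= 64]
    expected <- matrix(NA_real_, 16, 16)
    f <- switch(slab$projection, mean = mean, min = min, max = max)
    for (b in 1:16) for (a in 1:16) {
      vals <- fl$intensity[b, a, rows]
      vals <- vals[!is.na(vals)]
      if (length(vals) > 0) expected[b, a] <- f(vals)
    }
    expect_identical(img$pixels, expected)
  }
})

test_that("mean projection is linear and additive over slab partitions", {
  set.seed(7)
  geom <- voxel_geometry(c(375, 375), 5, c(12, 12, 64))
  arr <- array(runif(12 * 12 * 64, 0, 0.5), c(12, 12, 64))
  v <- oct_volume(arr, geom)
  ss <- flat_surfaces(geom, 80, 120, 200, 250)
  fl <- flatten(v, ss, "ipl_inl")
  img_full <- make_enface(fl, slab_spec("ipl_inl", 0, 100))
  # linearity
  fl2 <- flatten(oct_volume(arr / 2, geom), ss, "ipl_inl")
  img_half <- make_enface(fl2, slab_spec("ipl_inl", 0, 100))
  expect_equal(img_half$pixels, img_full$pixels / 2)
  # partition additivity at a voxel-aligned split
  img_a <- make_enface(fl, slab_spec("ipl_inl", 0, 40))
  img_b <- make_enface(fl, slab_spec("ipl_inl", 40, 60))
  expect_equal((40 * img_a$pixels + 60 * img_b$pixels) / 100,
               img_full$pixels, tolerance = 1e-12)
})

test_that("the standard slabs encode the published depths", {
  slabs <- standard_slabs()
  expect_equal(slabs$segment1$reference_surface, "ipl_inl")
  expect_equal(slabs$segment1$depth_um, 50)
  expect_equal(slabs$segment1$offset_um, 0)
  # Segment 2: inferior boundary 70 um above the RPE, 50 um scan depth
  expect_equal(slabs$segment2$reference_surface, "rpe")
  expect_equal(slabs$segment2$offset_um + slabs$segment2$depth_um, -70)
  expect_equal(slabs$segment2$offset_um, -120)
  expect_equal(slabs$surface$depth_um, 0)
  expect_equal(slabs$surface$reference_surface, "ilm")
  expect_error(slab_spec("ilm", 0, -5), "depth_um")
})

test_that("Segment-1/Segment-2 images of an FC phantom show fluid only at Segment 1", {
  ph <- generate_phantom(tiny_spec(fluid_config = fc_pocket(0.4)))
  ss <- segment_surfaces(ph$volume)
  slabs <- standard_slabs()
  img1 <- make_enface(flatten(ph$volume, ss, "ipl_inl"), slabs$segment1)
  img2 <- make_enface(flatten(ph$volume, ss, "rpe"), slabs$segment2)
  f1 <- detect_fluid(img1)
  f2 <- detect_fluid(img2)
  pos <- lateral_positions(ph$volume$geometry)
  expect_gt(nrow(f1$regions), 0L)
  expect_true(all(pos$r_mm[f1$mask] <= 0.5))
  expect_identical(nrow(f2$regions), 0L)
})

test_that("flattening at the ILM preserves sub-ILM fold lines of an ERM phantom", {
  ph <- generate_phantom(tiny_spec(erm_config = list(fold_depth_um = 60),
                                   seed = 13))
  ss <- segment_surfaces(ph$volume)
  fl <- flatten(ph$volume, ss, "ilm")
  img <- make_enface(fl, slab_spec("ilm", 30, 0))
  med <- stats::median(img$pixels, na.rm = TRUE)
  expect_gt(sum(img$pixels < 0.5 * med, na.rm = TRUE), 20)
})
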