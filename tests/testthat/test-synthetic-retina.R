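test_that("a fluid-free spec yields the control phantom", {
  ph <- generate_phantom(tiny_spec())
  expect_identical(ph$truth$type_label, "control")
  expect_false(any(ph$truth$fluid_mask))
  expect_false(any(ph$truth$srf_mask))
})

test_that("a foveal Henle cyst yields FC/NF and diffuse sheets plus SRF yield DF/DF + SF", {
  ph <- generate_phantom(tiny_spec(fluid_config = fc_pocket(0.4)))
  expect_identical(ph$truth$type_label, "FC/NF")
  ph2 <- generate_phantom(tiny_spec(
    fluid_config = df_pockets(),
    srf_config = list(radius_mm = 0.7, height_um = 80)))
  expect_identical(ph2$truth$type_label, "DF/DF + SF")
  expect_true(any(ph2$truth$srf_mask))
})

test_that("painted voxels and truth surfaces are mutually consistent", {
  ph <- generate_phantom(tiny_spec(fluid_config = fc_pocket(0.4)))
  V <- ph$volume$intensity
  tr <- ph$truth
  # fluid voxels carry the fluid reflectivity before noise
  expect_true(all(V[tr$fluid_mask] == 0.05))
  # surface ordering holds everywhere
  s <- tr$surfaces
  expect_true(all(s$ilm < s$ipl_inl & s$ipl_inl < s$ez & s$ez < s$rpe))
  # voxels just above the ILM are vitreous, just below are inner retina
  geom <- ph$volume$geometry
  for (i in c(1, 20, 40)) {
    above <- depth_to_index(s$ilm[i, i] - 8, geom)
    below <- depth_to_index(s$ilm[i, i] + 8, geom)
    expect_lt(V[i, i, above], 0.1)
    expect_gt(V[i, i, below], 0.3)
  }
})

test_that("phantom generation is deterministic under a fixed seed", {
  spec <- tiny_spec(fluid_config = fc_pocket(0.3), amplitude = 0.15, seed = 9,
                    erm_config = list(fold_depth_um = 40))
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$intensity, b$volume$intensity)
  expect_identical(a$truth$surfaces, b$truth$surfaces)
})

test_that("invalid fluid pockets are rejected with a diagnostic", {
  expect_error(fluid_pocket("Henle", radius_mm = -1), "radius")
  expect_error(generate_phantom(tiny_spec(fluid_config = list(
    fluid_pocket("Henle", "cystoid_cluster", c(0, 0), 0.3,
                 height_um = 200)))), "band thickness")
  expect_error(generate_phantom(tiny_spec(fluid_config = list(
    fluid_pocket("INL", "cystoid_cluster", c(30, 0), 0.3)))),
    "outside the scanned area")
})

test_that("the preset cohort factory honours counts, labels and seeds", {
  one <- preset_cohort(c("FC/NF" = 1L), seed = 3, speckle = 0,
                      n_ascans = c(48L, 48L), axial_extent_um = 900,
                      rpe_depth_um = 620)
  expect_length(one, 1L)
  expect_identical(one[[1]]$truth$type_label, "FC/NF")
  counts <- c("FC/NF" = 2L, "DF/DF" = 1L, control = 1L)
  specs <- preset_cohort(counts, seed = 5, as = "spec")
  expect_length(specs, 4L)
  specs2 <- preset_cohort(counts, seed = 5, as = "spec")
  expect_identical(specs, specs2)
  specs3 <- preset_cohort(counts, seed = 6, as = "spec")
  expect_false(identical(specs, specs3))
  expect_error(preset_cohort(c(bogus = 1L)), "named")
})

test_that("re-deriving labels from truth surfaces recovers every preset type", {
  counts <- stats::setNames(rep(1L, 6), c(observed_types(), "control"))
  specs <- preset_cohort(counts, seed = 21, speckle = 0, as = "spec")
  for (s in specs) {
    s$n_ascans <- c(64L, 64L); s$axial_extent_um <- 900; s$rpe_depth_um <- 620
    ph <- generate_phantom(s)
    res <- classify_eye(ph$volume, surfaces = ph$truth$surfaces)
    got <- if (res$classification$is_dme) res$classification$label else "control"
    expect_identical(got, ph$truth$type_label)
  }
})
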