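test_that("CST equals the analytic zone mean of a flat phantom", {
  # disable the foveal pit: the retina is uniformly 310 um thick
  spec <- tiny_spec(foveal_pit = list(inner_frac = 0, inl_frac = 0,
                                      sigma_mm = 0.35))
  ph <- generate_phantom(spec)
  cst_truth <- central_subfield_thickness(ph$truth$surfaces,
                                          ph$volume$geometry)
  expect_equal(cst_truth, 310, tolerance = 1e-9)
  ss <- segment_surfaces(ph$volume)
  cst_est <- central_subfield_thickness(ss, ph$volume$geometry)
  expect_lt(abs(cst_est - 310), ph$volume$geometry$axial_spacing_um)
  # flat retina: CST does not depend on where the fovea is placed
  geom2 <- ph$volume$geometry
  geom2$fovea_index <- c(20L, 44L)
  expect_equal(central_subfield_thickness(ph$truth$surfaces, geom2),
               cst_truth)
})

test_that("an SRF dome of height h raises CST by about h", {
  base <- generate_phantom(tiny_spec(seed = 4))
  dome <- generate_phantom(tiny_spec(
    srf_config = list(radius_mm = 0.9, height_um = 80), seed = 4))
  d <- central_subfield_thickness(dome$truth$surfaces, dome$volume$geometry) -
    central_subfield_thickness(base$truth$surfaces, base$volume$geometry)
  expect_lt(abs(d - 80), 10)
})

test_that("EZ disruption is judged on the central 3 mm of the cardinal scans", {
  gap <- generate_phantom(tiny_spec(
    ez_gap_config = list(center_mm = c(0, 0), radius_mm = 0.3)))
  expect_true(ez_disruption(gap$volume, segment_surfaces(gap$volume)))
  intact <- generate_phantom(tiny_spec(seed = 2))
  expect_false(ez_disruption(intact$volume, segment_surfaces(intact$volume)))
  far <- generate_phantom(tiny_spec(
    ez_gap_config = list(center_mm = c(2.5, 0), radius_mm = 0.3)))
  expect_false(ez_disruption(far$volume, segment_surfaces(far$volume)))
  expect_false(far$truth$ez_disrupted)
  # off-scan gap: does not touch either cardinal B-scan
  off <- generate_phantom(tiny_spec(
    ez_gap_config = list(center_mm = c(0.8, 0.8), radius_mm = 0.3)))
  expect_false(ez_disruption(off$volume, segment_surfaces(off$volume)))
  expect_false(off$truth$ez_disrupted)
})

test_that("ERM detection is present/absent and scale invariant", {
  erm <- generate_phantom(tiny_spec(erm_config = list(fold_depth_um = 50),
                                    seed = 8))
  ss <- segment_surfaces(erm$volume)
  img <- make_enface(flatten(erm$volume, ss, "ilm"), standard_slabs()$surface)
  expect_true(detect_erm(img))
  dim_img <- img
  dim_img$pixels <- img$pixels * 0.4
  expect_true(detect_erm(dim_img))
  clean <- generate_phantom(tiny_spec(seed = 9))
  ss2 <- segment_surfaces(clean$volume)
  img2 <- make_enface(flatten(clean$volume, ss2, "ilm"),
                      standard_slabs()$surface)
  expect_false(detect_erm(img2))
})

test_that("fold depth is recovered within one depth step", {
  for (depth in c(40, 60)) {
    ph <- generate_phantom(tiny_spec(erm_config = list(fold_depth_um = depth),
                                     seed = 15))
    ss <- segment_surfaces(ph$volume)
    fl <- flatten(ph$volume, ss, "ilm")
    mdrf10 <- max_depth_retinal_folds(fl, step_um = 10)
    expect_lte(abs(mdrf10 - depth), 10)
    # halving the step never loses precision
    mdrf5 <- max_depth_retinal_folds(fl, step_um = 5)
    expect_lte(abs(mdrf5 - depth), abs(mdrf10 - depth) + 5)
  }
  smooth <- generate_phantom(tiny_spec(seed = 16))
  ss <- segment_surfaces(smooth$volume)
  expect_identical(max_depth_retinal_folds(flatten(smooth$volume, ss, "ilm")),
                   0)
})

test_that("biomarker truth is recovered on noise-free phantoms", {
  spec <- tiny_spec(fluid_config = fc_pocket(0.35),
                    erm_config = list(fold_depth_um = 50),
                    ez_gap_config = list(center_mm = c(0, 0),
                                         radius_mm = 0.3),
                    seed = 23)
  ph <- generate_phantom(spec)
  bm <- measure_biomarkers(ph$volume)
  expect_true(bm$ez_disrupted)
  expect_true(bm$erm_present)
  expect_lte(abs(bm$mdrf_um - 50), 10)
  truth_cst <- central_subfield_thickness(ph$truth$surfaces,
                                          ph$volume$geometry)
  # coarse 94 um lateral grid: allow a little over one axial voxel
  expect_lt(abs(bm$cst_um - truth_cst), 8)
})

test_that("decimal acuity converts to logMAR", {
  expect_equal(decimal_to_logmar(1.0), 0)
  expect_equal(decimal_to_logmar(0.1), 1)
  expect_equal(decimal_to_logmar(0.5), 0.3010300, tolerance = 1e-6)
  expect_error(decimal_to_logmar(0), "positive")
  expect_error(decimal_to_logmar(-1), "positive")
})
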