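test_that("phantom generation is reproducible and respects the label convention", {
  spec <- phantom_spec(n_slices = 5)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$annotation$voxels, b$annotation$voxels)
  expect_identical(a$full$voxels, b$full$voxels)
  expect_identical(sort(unique(as.vector(a$annotation$voxels))), c(0L, 1L, 2L))
  expect_identical(sort(unique(as.vector(a$full$voxels))), c(0L, 1L, 2L, 3L))
})

test_that("every phantom slice has nonempty TL, FL and an inter-lumen gap", {
  spec <- phantom_spec(n_slices = 8, flap_thickness = 1.5, flap_offset = 10)
  ph <- generate_phantom(spec)
  for (z in seq_len(spec$n_slices)) {
    grid <- ph$annotation$voxels[z, , ]
    expect_gt(sum(grid == 1L), 0)
    expect_gt(sum(grid == 2L), 0)
    expect_gt(sum(ph$full$voxels[z, , ] == 3L), 0)
  }
})

test_that("an offset chord makes TL the minority segment", {
  spec <- phantom_spec(outer_diameter = 50, flap_offset = 10,
                       flap_thickness = 2.4, n_slices = 3)
  ph <- generate_phantom(spec)
  expect_equal(ph$truth$aortic_diameter, 50)
  expect_lt(ph$truth$tl_area, ph$truth$fl_area)
  grid <- ph$annotation$voxels[2, , ]
  expect_lt(sum(grid == 1L), sum(grid == 2L))
})

test_that("the symmetric phantom matches the closed-form circular-segment area", {
  # diameter chord, 2 mm band, 40 mm lumen: both sides are segments cut
  # 1 mm from centre, area R^2 (theta - sin theta) / 2 with cos(theta/2) = 1/20
  spec <- phantom_spec(outer_diameter = 40, flap_offset = 0,
                       flap_thickness = 2, n_slices = 2,
                       grid_shape = c(96L, 96L))
  ph <- generate_phantom(spec)
  R <- 20
  theta <- 2 * acos(1 / R)
  seg <- R^2 * (theta - sin(theta)) / 2
  expect_equal(ph$truth$tl_area, seg, tolerance = 1e-12)
  expect_equal(ph$truth$fl_area, seg, tolerance = 1e-12)
})

test_that("rasterized lumen areas agree with the analytic truth across random specs", {
  # coarse grid at the reference in-plane pixel, and a 10x finer oracle grid
  set.seed(21)
  for (i in 1:20) {
    od <- runif(1, 35, 55)
    th <- runif(1, 1.5, 3.5)
    of <- runif(1, 0, 10)
    an <- runif(1, 0, pi)
    spec <- phantom_spec(n_slices = 1, outer_diameter = od, flap_thickness = th,
                         flap_offset = of, flap_angle = an,
                         centerline_amplitude = 0)
    ph <- generate_phantom(spec)
    grid <- ph$annotation$voxels[1, , ]
    tl_px <- sum(grid == 1L) * 0.8242^2
    fl_px <- sum(grid == 2L) * 0.8242^2
    expect_lt(abs(tl_px - ph$truth$tl_area) / ph$truth$tl_area, 0.02)
    expect_lt(abs(fl_px - ph$truth$fl_area) / ph$truth$fl_area, 0.02)
    if (i <= 3) {
      fine <- raster_segment_areas(od, th, of, an, 0.08242)
      areas <- sort(c(ph$truth$tl_area, ph$truth$fl_area))
      expect_equal(sort(unname(fine)), areas, tolerance = 0.005)
    }
  }
})

test_that("invalid phantom geometry is rejected with the violated constraint", {
  expect_error(phantom_spec(flap_thickness = 60, outer_diameter = 50),
               "flap_thickness", class = "taadmorph_validation_error")
  expect_error(phantom_spec(flap_offset = 24, flap_thickness = 2.4,
                            outer_diameter = 50),
               "inside the lumen", class = "taadmorph_validation_error")
  expect_error(phantom_spec(outer_diameter = 90, grid_shape = c(96L, 96L)),
               "margin", class = "taadmorph_validation_error")
})

test_that("degradation with an all-zero spec is the identity", {
  ph <- generate_phantom(phantom_spec(n_slices = 4))
  d <- degrade_prediction(ph$annotation, degradation_spec(0, 0, 0, seed = 9))
  expect_identical(d$voxels, ph$annotation$voxels)
})

test_that("degradation is seed-deterministic and bounded by its invariants", {
  ph <- generate_phantom(phantom_spec(n_slices = 6))
  spec <- degradation_spec(0.9, 0.05, 1L, seed = 4)
  a <- degrade_prediction(ph$annotation, spec)
  b <- degrade_prediction(ph$annotation, spec)
  expect_identical(a$voxels, b$voxels)
  expect_true(all(a$voxels %in% 0:2))
  expect_error(degradation_spec(flip_fraction = 1),
               class = "taadmorph_validation_error")
  expect_error(degradation_spec(boundary_shift_mm = -1),
               class = "taadmorph_validation_error")
  # boundary shift bounded relative to the phantom it degrades
  expect_error(degrade_prediction(ph$annotation,
                                  degradation_spec(boundary_shift_mm = 20)),
               class = "taadmorph_validation_error")
})

test_that("full dropout zeroes every slice so recall vanishes", {
  ph <- generate_phantom(phantom_spec(n_slices = 4))
  d <- degrade_prediction(ph$annotation,
                          degradation_spec(0, 0, 4L, seed = 2))
  expect_true(all(d$voxels == 0L))
  suppressWarnings({
    pm <- patient_metrics(ph$annotation, d)
  })
  expect_true(all(pm$recall == 0))
})

test_that("moderate degradation yields overlap strictly between 0 and 1", {
  ph <- generate_phantom(phantom_spec(n_slices = 6))
  d <- degrade_prediction(ph$annotation,
                          degradation_spec(0.9, 0.05, 0L, seed = 8))
  m <- compute_metrics(confusion_counts(ph$annotation, d, 1L))
  expect_gt(m$dsc, 0)
  expect_lt(m$dsc, 1)
})

test_that("synthetic intensities are deterministic with configured levels", {
  ph <- generate_phantom(phantom_spec(n_slices = 3))
  img0 <- synthesize_intensity(ph$full, noise_sd = 0)
  expect_lte(length(unique(as.vector(img0))), 4L)
  i1 <- synthesize_intensity(ph$full, noise_sd = 30, seed = 5)
  i2 <- synthesize_intensity(ph$full, noise_sd = 30, seed = 5)
  expect_identical(i1, i2)
  # per-label mean within 3 standard errors of the configured level
  lum <- ph$full$voxels == 1L
  n <- sum(lum)
  expect_gt(n, 1e3)
  expect_lt(abs(mean(i1[lum]) - 350), 3 * 30 / sqrt(n))
  expect_error(synthesize_intensity(ph$full, noise_sd = -1),
               class = "taadmorph_validation_error")
})
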