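test_that("maximum Feret diameter matches simple cases and the all-pairs oracle", {
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  expect_equal(max_diameter(m1, c(1, 1)), 0)

  m2 <- matrix(FALSE, 5, 6); m2[1, 1] <- TRUE; m2[4, 5] <- TRUE
  expect_equal(max_diameter(m2, c(1, 1)), 5)  # 3-4-5 triangle

  expect_error(max_diameter(matrix(FALSE, 3, 3)),
               class = "taadmorph_validation_error")

  # random masks vs exhaustive all-pairs distance
  set.seed(41)
  for (i in 1:5) {
    m <- matrix(runif(30 * 30) < 0.2, 30, 30)
    if (sum(m) < 2) next
    sp <- c(0.8242, 0.8242)
    idx <- which(m, arr.ind = TRUE)
    pts <- sweep(idx - 1, 2, sp, "*")
    d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
    expect_equal(max_diameter(m, sp), sqrt(max(d2)), tolerance = 1e-12)
  }

  # rasterized 50 mm disc at the reference pixel size
  r_px <- 25 / 0.8242
  dm <- outer((1:80 - 40)^2, (1:80 - 40)^2, "+") <= r_px^2
  expect_lt(abs(max_diameter(dm, c(0.8242, 0.8242)) - 50), 2 * in_plane_diag)
})

test_that("region area is pixel count times pixel area and additive", {
  expect_equal(region_area(matrix(FALSE, 4, 4), c(1, 1)), 0)
  m <- matrix(FALSE, 20, 20); m[1:10, 1:10] <- TRUE
  expect_equal(region_area(m, c(0.8242, 0.8242)), 100 * 0.8242^2)
  expect_equal(round(region_area(m, c(0.8242, 0.8242)), 2), 67.93)
  m2 <- matrix(FALSE, 20, 20); m2[15:18, 15:18] <- TRUE
  expect_equal(region_area(m | m2, c(1, 1)),
               region_area(m, c(1, 1)) + region_area(m2, c(1, 1)))
})

test_that("mean thickness recovers band widths including rotated bands", {
  r <- matrix(FALSE, 20, 50); r[8:12, 5:45] <- TRUE
  expect_lt(abs(mean_thickness(r, c(1, 1)) - 5), 0.5)

  # the same band rotated 30 degrees and re-rasterized
  y <- 0:59; x <- 0:59
  s <- outer(y - 30, x - 30, function(a, b) a * cos(pi / 6) + b * sin(pi / 6))
  t <- outer(y - 30, x - 30, function(a, b) -a * sin(pi / 6) + b * cos(pi / 6))
  rot <- abs(s) <= 2.5 & abs(t) <= 20
  expect_lt(abs(mean_thickness(rot, c(1, 1)) - 5) / 5, 0.10)
  # cross-check estimator: area over skeleton length
  expect_lt(abs(taadmorph:::thickness_area_over_length(rot, c(1, 1)) - 5) / 5,
            0.15)

  # single-pixel line degenerates to one pixel spacing with a warning
  ln <- matrix(FALSE, 10, 20); ln[5, 3:17] <- TRUE
  expect_warning(th <- mean_thickness(ln, c(1, 1)), "single-pixel")
  expect_equal(th, 1)
  expect_error(mean_thickness(matrix(FALSE, 3, 3)),
               class = "taadmorph_validation_error")
})

test_that("slice morphometry satisfies its ordering invariants", {
  # offset chord: TL is the minority side, diameters nested in the aorta
  ph <- generate_phantom(phantom_spec(n_slices = 1, flap_offset = 8,
                                      centerline_amplitude = 0))
  out <- extract_flap_volume(ph$annotation)
  reg <- taadmorph:::regions_from_grid(out$voxels[1, , ], c(0.8242, 0.8242))
  sm <- slice_morphometry(reg, z = 1)
  expect_lt(sm$tl_area, sm$fl_area)
  expect_gte(sm$aortic_diameter, max(sm$tl_diameter, sm$fl_diameter))
  expect_gt(sm$flap_thickness, 0)

  # symmetric chord: equal areas up to rasterization
  ph0 <- generate_phantom(phantom_spec(n_slices = 1, flap_offset = 0,
                                       centerline_amplitude = 0))
  out0 <- extract_flap_volume(ph0$annotation)
  reg0 <- taadmorph:::regions_from_grid(out0$voxels[1, , ], c(0.8242, 0.8242))
  sm0 <- slice_morphometry(reg0, z = 1)
  expect_lt(abs(sm0$tl_area - sm0$fl_area) / sm0$fl_area, 0.05)

  # empty region is rejected
  reg_empty <- reg
  reg_empty$flap_mask[] <- FALSE
  expect_error(slice_morphometry(reg_empty, 1),
               class = "taadmorph_validation_error")
})

test_that("patient averages equal single-slice values for a straight tube", {
  ph <- generate_phantom(phantom_spec(n_slices = 4, centerline_amplitude = 0))
  out <- extract_flap_volume(ph$annotation)
  pm <- patient_morphometry(out, patient_id = "p")
  reg <- taadmorph:::regions_from_grid(out$voxels[1, , ], c(0.8242, 0.8242))
  sm <- slice_morphometry(reg, 1)
  expect_equal(pm$n_slices_used, 4)
  for (f in c("aortic_diameter", "tl_diameter", "fl_diameter",
              "tl_area", "fl_area", "flap_thickness"))
    expect_equal(pm[[f]], sm[[f]])
  # slice range excluding everything leads to the exclusion outcome
  expect_error(patient_morphometry(out, slice_range = c(10, 20)),
               class = "taadmorph_exclusion")
})

test_that("drifting-centerline averages stay near the analytic truth", {
  ph <- generate_phantom(phantom_spec(n_slices = 6, centerline_amplitude = 5))
  out <- extract_flap_volume(ph$annotation)
  pm <- patient_morphometry(out, patient_id = "drift")
  expect_lt(abs(pm$aortic_diameter - ph$truth$aortic_diameter), in_plane_diag)
  expect_lt(abs(pm$tl_area - ph$truth$tl_area) / ph$truth$tl_area, 0.03)
  expect_lt(abs(pm$fl_area - ph$truth$fl_area) / ph$truth$fl_area, 0.03)
  expect_lt(abs(pm$flap_thickness - ph$truth$flap_thickness), in_plane_px)
})

test_that("relative errors average per patient, not over the averages", {
  gt <- data.frame(patient_id = c("a", "b"), n_slices_used = 1,
                   aortic_diameter = c(50, 100), tl_diameter = c(30, 60),
                   fl_diameter = c(45, 90), tl_area = c(500, 1000),
                   fl_area = c(900, 1800), flap_thickness = c(2, 3))
  pred <- gt
  pred$aortic_diameter <- c(45, 110)
  cmp <- compare_morphometry(gt, pred)
  row <- cmp[cmp$field == "aortic_diameter", ]
  expect_equal(row$mean_relative_error, (0.10 + 0.10) / 2)
  expect_equal(row$gt_average, 75)
  expect_equal(row$pred_average, 77.5)
  # identity gives zero everywhere
  cmp0 <- compare_morphometry(gt, gt)
  expect_true(all(cmp0$mean_relative_error == 0))

  # mixed-sign per-patient errors dominate the error of the averages
  set.seed(13)
  for (i in 1:20) {
    g <- runif(8, 50, 100)
    p <- g * (1 + runif(8, -0.2, 0.2))
    per_patient <- mean(abs(p - g) / g)
    of_means <- abs(mean(p) - mean(g)) / mean(g)
    expect_gte(per_patient + 1e-12, of_means)
  }

  expect_error(compare_morphometry(gt, pred[1, ]),
               class = "taadmorph_validation_error")
})
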