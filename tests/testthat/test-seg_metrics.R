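make_vol <- function(arr, spacing = c(1, 1, 1)) label_volume(arr, spacing)

test_that("confusion counts match direct substitution and the brute-force oracle", {
  # identity: fp = fn = 0
  set.seed(5)
  arr <- array(sample(0:2, 60, replace = TRUE), c(3, 4, 5))
  v <- make_vol(arr)
  cc <- confusion_counts(v, v, 1L)
  expect_equal(cc$fp, 0)
  expect_equal(cc$fn, 0)
  expect_equal(cc$tp, sum(arr == 1L))
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, length(arr))

  # all-background prediction
  gt <- array(0L, c(4, 5, 5)); gt[1:10] <- 1L
  pr <- array(0L, c(4, 5, 5))
  cc2 <- confusion_counts(make_vol(gt), make_vol(pr), 1L)
  expect_equal(unlist(cc2[c("tp", "tn", "fp", "fn")]),
               c(tp = 0, tn = 90, fp = 0, fn = 10))

  # random pair vs exhaustive triple-loop oracle
  g <- array(sample(0:2, 20 * 20 * 5, replace = TRUE), c(5, 20, 20))
  p <- array(sample(0:2, 20 * 20 * 5, replace = TRUE), c(5, 20, 20))
  for (lab in 1:2) {
    fast <- confusion_counts(make_vol(g), make_vol(p), lab)
    slow <- brute_confusion(g, p, lab)
    expect_identical(unlist(fast[c("tp", "tn", "fp", "fn")]),
                     c(tp = slow$tp, tn = slow$tn, fp = slow$fp, fn = slow$fn))
  }
})

test_that("metric formulas follow direct substitution with NA for undefined ratios", {
  m <- compute_metrics(list(tp = 8, tn = 90, fp = 1, fn = 1))
  expect_equal(m$accuracy, 0.98)
  expect_equal(m$precision, 8 / 9)
  expect_equal(m$recall, 8 / 9)
  expect_equal(m$iou, 0.8)
  expect_equal(m$dsc, 8 / 9)

  w <- capture_warnings(
    m0 <- compute_metrics(list(tp = 0, tn = 100, fp = 0, fn = 0)))
  expect_length(w, 4)  # precision, recall, IoU, DSC all undefined
  expect_true(all(grepl("undefined", w)))
  expect_equal(m0$accuracy, 1)
  expect_true(all(is.na(c(m0$precision, m0$recall, m0$iou, m0$dsc))))
})

test_that("DSC and IoU satisfy dsc = 2 iou / (1 + iou) on random counts", {
  set.seed(17)
  for (i in 1:1000) {
    cts <- as.list(stats::setNames(sample(1:500, 4, replace = TRUE),
                                   c("tp", "tn", "fp", "fn")))
    m <- compute_metrics(cts)
    expect_equal(m$dsc, 2 * m$iou / (1 + m$iou), tolerance = 1e-12)
    # tn only inflates accuracy: accuracy >= iou when tn > 0
    expect_gte(m$accuracy, m$iou)
  }
})

test_that("shape and spacing mismatches are reported with both operands", {
  a <- make_vol(array(0L, c(2, 3, 4)))
  b <- make_vol(array(0L, c(2, 3, 5)))
  expect_error(confusion_counts(a, b, 1L), "2x3",
               class = "taadmorph_validation_error")
  d <- label_volume(array(0L, c(2, 3, 4)), c(2, 1, 1))
  expect_error(confusion_counts(a, d, 1L), "spacing",
               class = "taadmorph_validation_error")
})

test_that("Hausdorff distance reproduces simple geometric cases", {
  g <- array(0L, c(1, 4, 5)); g[1, 1, 1] <- 1L
  p <- array(0L, c(1, 4, 5)); p[1, 4, 5] <- 1L
  # offsets (0, 3, 4) at unit spacing: a 3-4-5 triangle
  expect_equal(hausdorff_distance(make_vol(g), make_vol(p), 1L), 5)
  expect_equal(hausdorff_distance(make_vol(g), make_vol(g), 1L), 0)

  # asymmetric directed distances: {0, 10} vs {0}
  g2 <- array(0L, c(1, 1, 11)); g2[1, 1, c(1, 11)] <- 1L
  p2 <- array(0L, c(1, 1, 11)); p2[1, 1, 1] <- 1L
  expect_equal(hausdorff_distance(make_vol(g2), make_vol(p2), 1L), 10)

  # physical anisotropic spacing scales coordinates
  expect_equal(hausdorff_distance(make_vol(g2, c(1, 1, 0.5)),
                                  make_vol(p2, c(1, 1, 0.5)), 1L), 5)
  expect_equal(hausdorff_distance(make_vol(g2, c(1, 1, 0.5)),
                                  make_vol(p2, c(1, 1, 0.5)), 1L,
                                  units = "voxel"), 10)

  # empty set: +Inf with a warning
  expect_warning(hd <- hausdorff_distance(make_vol(g), make_vol(g * 0L), 1L),
                 "absent")
  expect_identical(hd, Inf)
})

test_that("Hausdorff via distance transforms equals the all-pairs oracle", {
  set.seed(23)
  sp <- c(1.25, 0.8242, 0.8242)
  for (i in 1:10) {
    d <- c(4, 7, 8)
    g <- array(sample(c(0L, 1L), prod(d), TRUE, c(0.8, 0.2)), d)
    p <- array(sample(c(0L, 1L), prod(d), TRUE, c(0.8, 0.2)), d)
    if (!any(g == 1L) || !any(p == 1L)) next
    fast <- hausdorff_distance(make_vol(g, sp), make_vol(p, sp), 1L)
    slow <- brute_hausdorff(which(g == 1L, arr.ind = TRUE),
                            which(p == 1L, arr.ind = TRUE), sp)
    expect_equal(fast, slow, tolerance = 1e-9)
  }
})

test_that("metric symmetry and permutation invariance hold", {
  set.seed(31)
  d <- c(4, 8, 8)
  g <- array(sample(0:2, prod(d), TRUE), d)
  p <- array(sample(0:2, prod(d), TRUE), d)
  gv <- make_vol(g); pv <- make_vol(p)
  for (lab in 1:2) {
    m1 <- compute_metrics(confusion_counts(gv, pv, lab))
    m2 <- compute_metrics(confusion_counts(pv, gv, lab))
    expect_equal(m1$precision, m2$recall)
    expect_equal(m1$recall, m2$precision)
    # Hausdorff is symmetric in its arguments
    expect_equal(hausdorff_distance(gv, pv, lab),
                 hausdorff_distance(pv, gv, lab))
  }
  # identical slice permutation leaves everything unchanged
  perm <- sample(d[1])
  gp <- make_vol(g[perm, , ]); pp <- make_vol(p[perm, , ])
  expect_identical(unlist(confusion_counts(gv, pv, 1L)[1:4]),
                   unlist(confusion_counts(gp, pp, 1L)[1:4]))
})

test_that("cross-validation folds partition patients near-evenly and reproducibly", {
  lay <- make_cv_layout(sprintf("p%02d", 1:24), k = 4, seed = 7)
  expect_equal(unname(table(lay$fold)), rep(6L, 4), ignore_attr = TRUE)
  expect_setequal(lay$patient_id, sprintf("p%02d", 1:24))
  lay2 <- make_cv_layout(sprintf("p%02d", 1:24), k = 4, seed = 7)
  expect_identical(lay$fold, lay2$fold)

  lay5 <- make_cv_layout(letters[1:5], k = 4, seed = 1)
  expect_equal(sort(unname(table(lay5$fold)), decreasing = TRUE),
               c(2L, 1L, 1L, 1L), ignore_attr = TRUE)
  expect_error(make_cv_layout(letters[1:3], k = 4),
               class = "taadmorph_validation_error")
})

test_that("paired comparison computes t and Shapiro-Wilk with documented edge cases", {
  # zero variance: a == b elementwise
  a <- rnorm(10)
  expect_error(paired_comparison(a, a), "zero variance",
               class = "taadmorph_validation_error")
  # symmetric differences: t = 0, p = 1
  d <- c(-1, 0, 1, -2, 2)
  pc <- paired_comparison(d, rep(0, 5))
  expect_equal(pc$t_statistic, 0)
  expect_equal(pc$t_p, 1)
  expect_false(pc$significant)
  # frozen reference value (scipy.stats.shapiro) for a fixed n = 24 sample
  x <- c(4.1, 5.2, 3.8, 6.0, 5.5, 4.9, 5.1, 6.3, 4.4, 5.8, 5.0, 4.7,
         6.1, 5.4, 4.2, 5.9, 5.3, 4.6, 5.7, 5.0, 4.8, 6.2, 4.5, 5.6)
  pc2 <- paired_comparison(x, rep(0, 24))
  expect_equal(pc2$shapiro_w, 0.9764050, tolerance = 1e-3)
  # n < 3 and NA handling
  expect_error(paired_comparison(1:2, 2:3), class = "taadmorph_validation_error")
  expect_warning(pc3 <- paired_comparison(c(x, NA), c(rep(0, 24), 1)),
                 "excluded")
  expect_equal(pc3$n, 24)
})

test_that("per-patient metric tables summarise as mean/SD on the percent scale", {
  df <- data.frame(patient_id = rep(1:4, 2),
                   net = rep(c("a", "b"), each = 4),
                   label = "TL",
                   accuracy = c(0.99, 0.98, 0.97, 1.00, 0.95, 0.96, 0.94, 0.93),
                   precision = 0.9, recall = 0.9, iou = 0.8, dsc = 8 / 9,
                   hd = c(1, 2, 3, 4, 5, 6, 7, 8))
  s <- summarize_metrics(df)
  acc_a <- s[s$net == "a" & s$metric == "accuracy", ]
  expect_equal(acc_a$mean, mean(c(99, 98, 97, 100)))
  expect_equal(acc_a$sd, sd(c(99, 98, 97, 100)))
  hd_b <- s[s$net == "b" & s$metric == "hd", ]
  expect_equal(hd_b$mean, 6.5)  # HD stays in its own units
})
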