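test_that("module annotations tile the raster without degenerate boxes", {
  ann <- module_annotations()
  expect_equal(nrow(ann), 24)
  expect_equal(ann$x0[1], 0)
  expect_equal(ann$x1[24], 298)
  expect_true(all(ann$x1 > ann$x0))
  expect_true(all(ann$x0[-1] == ann$x1[-24]))  # contiguous tiling
  expect_true(all(ann$y0 >= 0 & ann$y1 <= 224))
})

test_that("ground-truth heatmaps peak at the annotation center with FWHM spread", {
  # 13x13 box: center falls exactly on a pixel center
  box <- list(x0 = 100, y0 = 100, x1 = 113, y1 = 113)
  hm <- make_gt_heatmap(box)
  expect_equal(dim(hm), c(224, 298))
  am <- which(hm == max(hm), arr.ind = TRUE)
  expect_equal(unname(am[1, ]), c(107, 107))  # pixel centered at 106.5
  # isotropy: equal values at equal distances from the center
  expect_equal(hm[107, 107 + 5], hm[107 + 5, 107])
  expect_equal(hm[107, 107 - 5], hm[107, 107 + 5])
  # spread: recovering sigma from a pixel at distance 6 must give the
  # FWHM convention sigma = diameter / 2.355, i.e. the value at radius
  # diameter/2 is half the peak
  v6 <- hm[107, 113]
  sigma_rec <- sqrt(-6^2 / (2 * log(v6)))
  expect_equal(sigma_rec, 13 / (2 * sqrt(2 * log(2))), tolerance = 1e-9)
  expect_equal(exp(-(13 / 2)^2 / (2 * sigma_rec^2)), 0.5, tolerance = 1e-9)
  expect_error(make_gt_heatmap(list(x0 = 5, y0 = 5, x1 = 5, y1 = 9)),
               "degenerate")
  expect_error(make_gt_heatmap(list(x0 = -2, y0 = 0, x1 = 5, y1 = 9)),
               "bounds")
})

test_that("soft-argmax decodes peaks, uniform maps, and symmetric doublets", {
  m <- matrix(0, 20, 30)
  m[7, 21] <- 1
  expect_equal(soft_argmax(m, weight = 500), c(row = 6.5, col = 20.5),
               tolerance = 1e-6)
  u <- matrix(1, 20, 30)
  expect_equal(soft_argmax(u), c(row = 10, col = 15))
  two <- matrix(0, 21, 21)
  two[5, 11] <- 1; two[17, 11] <- 1
  expect_equal(soft_argmax(two, weight = 50), c(row = 10.5, col = 10.5))
  expect_error(soft_argmax(matrix(c(1, NA, 1, 1), 2)), "finite")
  expect_error(soft_argmax(u, weight = -1), "weight")
})

test_that("soft-argmax of a ground-truth heatmap returns the annotation center", {
  ann <- module_annotations()
  for (m in c(2, 12, 23)) {
    hm <- make_gt_heatmap(ann[m, ])
    sa <- soft_argmax(hm)
    expect_lt(abs(sa["col"] - (ann$x0[m] + ann$x1[m]) / 2), 0.5)
    expect_lt(abs(sa["row"] - (ann$y0[m] + ann$y1[m]) / 2), 0.5)
  }
})

test_that("map losses vanish at the truth and are positive elsewhere", {
  ann <- module_annotations()
  gt <- make_gt_heatmap(ann[12, ])
  expect_equal(kl_map_loss(gt, gt), 0)
  expect_equal(mse_map_loss(gt, gt), 0)
  expect_equal(mse_coord_loss(gt, gt), 0)
  # KL non-negativity on arbitrary maps (Gibbs inequality)
  set.seed(4)
  for (i in 1:5) {
    a <- matrix(runif(48), 6, 8)
    b <- matrix(runif(48), 6, 8)
    expect_gte(kl_map_loss(a, b), 0)
  }
  expect_error(kl_map_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  expect_error(combined_map_loss(gt, gt, w_kl = 0.1, w_mse = 1), "w_kl > w_mse")
})

test_that("KL on a tiny map matches hand-computed sum p log(p/q)", {
  pred <- matrix(c(0.2, 0.8, 0.4, 0.6), 2, 2)
  gt <- matrix(c(1.0, 0.1, 0.3, 0.2), 2, 2)
  # independent arithmetic: explicit softmax then the definition
  p <- exp(gt) / sum(exp(gt))
  q <- exp(pred) / sum(exp(pred))
  expect_equal(kl_map_loss(pred, gt), sum(p * log(p / q)), tolerance = 1e-12)
})

test_that("the combined loss is strictly minimized at the truth over a shift grid", {
  ann <- module_annotations()
  gt <- make_gt_heatmap(ann[12, ])
  at_truth <- combined_map_loss(gt, gt)
  for (shift in c(-24, -12, 12, 24)) {
    shifted <- make_gt_heatmap(list(x0 = ann$x0[12] + shift, y0 = ann$y0[12],
                                    x1 = ann$x1[12] + shift, y1 = ann$y1[12]))
    expect_gt(combined_map_loss(shifted, gt), at_truth)
  }
})

test_that("IOU matches area arithmetic", {
  expect_equal(iou(list(x0 = 0, y0 = 0, x1 = 2, y1 = 2),
                   list(x0 = 0, y0 = 0, x1 = 2, y1 = 2)), 1)
  expect_equal(iou(list(x0 = 0, y0 = 0, x1 = 2, y1 = 2),
                   list(x0 = 5, y0 = 5, x1 = 7, y1 = 7)), 0)
  expect_equal(iou(list(x0 = 0, y0 = 0, x1 = 2, y1 = 2),
                   list(x0 = 1, y0 = 0, x1 = 3, y1 = 2)), 1 / 3)
})

test_that("heatmaps are assigned to the module they were drawn on", {
  ann <- module_annotations()
  for (m in seq(1, 24, by = 3)) {
    hm <- make_gt_heatmap(ann[m, ])
    expect_equal(assign_module(hm, ann), m)
  }
  expect_error(assign_module(matrix(0, 224, 298), ann), "positive")
})

test_that("shift histograms count ventriloquist displacements", {
  # perfect localizer
  h0 <- shift_histogram(1:24, 1:24)
  expect_equal(h0$shift_modules, 0)
  expect_equal(h0$relative_frequency, 1)
  # fully captured: predictions 4 modules right of the truth
  truth <- rep(3:18, 2)
  h4 <- shift_histogram(truth + 4, truth, geometry = array_geometry())
  expect_equal(h4$relative_frequency[h4$shift_modules == 4], 1)
  expect_equal(h4$shift_deg[h4$shift_modules == 4], 12)
  # mixed shifts normalize to 1 and keep interior zeros
  h <- shift_histogram(c(5, 5, 9, 2), c(5, 6, 5, 5))
  expect_equal(sum(h$relative_frequency), 1)
  expect_equal(h$shift_modules, -3:4)
  expect_error(shift_histogram(1:3, 1:4), "equal length")
})
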