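test_that("background estimation is the median of the designated region", {
  img <- labeled_image(matrix(10, 8, 8), 0.01,
                       rois = list(background = matrix(TRUE, 8, 8)))
  expect_equal(estimate_background(img), 10)
  px <- matrix(c(rep(0, 32), rep(20, 32)), 8, 8)
  img2 <- labeled_image(px, 0.01,
                        rois = list(background = matrix(TRUE, 8, 8)))
  expect_equal(estimate_background(img2), 10)
  img3 <- labeled_image(px, 0.01,
                        rois = list(background = matrix(FALSE, 8, 8)))
  expect_error(estimate_background(img3), "empty")
  # on generated noisy background: within 2% of the generator mean
  cfg <- synth_config(image_size = 128, background_mean = 50,
                      background_sd = 5, blobs_per_image = 0)
  gi <- gen_section_image(cfg, seed = 8)
  expect_lt(abs(estimate_background(gi) - 50) / 50, 0.02)
})

test_that("thresholding uses a strict background multiple", {
  px <- matrix(c(10, 30, 30.5, 61), 2, 2)
  img <- labeled_image(px, 0.01)
  m <- threshold_mask(img, background = 10, k = 3)
  expect_identical(as.vector(m), c(FALSE, FALSE, TRUE, TRUE))
  # k = 1.5 with zero background includes every positive pixel
  m0 <- threshold_mask(img, background = 0, k = 1.5)
  expect_true(all(m0))
  expect_error(threshold_mask(img, background = -1, k = 3))
})

test_that("cell counting uses 8-connected components with a size filter", {
  expect_equal(count_cells(matrix(FALSE, 10, 10))$count, 0)
  m <- matrix(FALSE, 12, 12)
  m[2:4, 2:4] <- TRUE
  m[8:10, 8:10] <- TRUE
  cc <- count_cells(m, min_area_px = 4)
  expect_equal(cc$count, 2)
  expect_equal(cc$centroids$row, c(3, 9))
  expect_equal(cc$centroids$col, c(3, 9))
  expect_equal(count_cells(m, min_area_px = 10)$count, 0)
  # diagonal touch merges under 8-connectivity
  d <- matrix(FALSE, 4, 4); d[1, 1] <- TRUE; d[2, 2] <- TRUE
  expect_equal(count_cells(d)$count, 1)
})

test_that("planted blob counts are recovered exactly", {
  hits <- vapply(1:25, function(s) {
    cfg <- synth_config(image_size = 128, blobs_per_image = 6)
    im <- gen_section_image(cfg, seed = s)
    bg <- estimate_background(im)
    cc <- count_cells(threshold_mask(im, bg, 3) & im$rois$cells,
                      min_area_px = 4)
    cc$count == attr(im, "truth")$n_blobs
  }, logical(1))
  expect_true(all(hits))
})

test_that("region metrics match arithmetic and the per-pixel oracle", {
  px <- matrix(0, 8, 8); px[2, 2:5] <- 100
  img <- labeled_image(px, 0.01, rois = list(r = matrix(TRUE, 8, 8)))
  m <- region_axon_metrics(img, "r", background = 10, k = 3)
  expect_equal(m$arborization_area_mm2, 4e-4)
  expect_equal(m$integrated_density, 400)
  # nothing above threshold
  m0 <- region_axon_metrics(img, "r", background = 1000, k = 3)
  expect_equal(m0$arborization_area_mm2, 0)
  expect_equal(m0$integrated_density, 0)
  expect_error(region_axon_metrics(img, "nope", 10), "unknown ROI")
  img_empty <- labeled_image(px, 0.01, rois = list(z = matrix(FALSE, 8, 8)))
  expect_error(region_axon_metrics(img_empty, "z", 10), "disjoint")

  for (s in 1:5) {
    cfg <- synth_config(image_size = 64, blobs_per_image = 2,
                        axon_area_px = 60)
    gi <- gen_section_image(cfg, seed = s)
    bg <- estimate_background(gi)
    for (roi in c("cells", "axon")) {
      got <- region_axon_metrics(gi, roi, bg, k = 3)
      want <- oracle_region_metrics(gi$pixels, gi$rois[[roi]], bg, 3,
                                    gi$pixel_size_mm)
      expect_identical(got$arborization_area_mm2, want$arborization_area_mm2)
      expect_identical(got$integrated_density, want$integrated_density)
    }
  }
})

test_that("per-cell intensities sum supra-threshold pixels in each mask", {
  px <- matrix(0, 8, 8)
  px[2:3, 2:3] <- 20   # cell 1: 4 px at 2x background
  mask1 <- matrix(FALSE, 8, 8); mask1[2:3, 2:3] <- TRUE
  mask2 <- matrix(FALSE, 8, 8); mask2[6:7, 6:7] <- TRUE
  img <- labeled_image(px, 0.01, cell_masks = list(mask1, mask2))
  got <- percell_intensity(img, background = 10, k = 1.5)
  expect_equal(got, c(4 * 20, 0))
  expect_error(percell_intensity(labeled_image(px, 0.01), 10), "cell masks")
  # planted puncta recovery on a zero-background image
  cfg <- synth_config(image_size = 96, blobs_per_image = 3,
                      background_mean = 0, background_sd = 0)
  gi <- gen_section_image(cfg, seed = 4)
  expect_equal(percell_intensity(gi, background = 0, k = 1.5),
               attr(gi, "truth")$cell_intensity)
})

test_that("metrics are monotone in k and covariant in pixel size", {
  cfg <- synth_config(image_size = 64, blobs_per_image = 2,
                      axon_area_px = 40)
  gi <- gen_section_image(cfg, seed = 12)
  bg <- estimate_background(gi)
  ks <- c(1, 1.5, 2, 3, 4)
  areas <- vapply(ks, function(k)
    region_axon_metrics(gi, "full", bg, k)$arborization_area_mm2, numeric(1))
  dens <- vapply(ks, function(k)
    region_axon_metrics(gi, "full", bg, k)$integrated_density, numeric(1))
  expect_true(all(diff(areas) <= 0))
  expect_true(all(diff(dens) <= 0))
  # halving the pixel size quarters the area of the same mask
  gi2 <- labeled_image(gi$pixels, gi$pixel_size_mm / 2, rois = gi$rois)
  a1 <- region_axon_metrics(gi, "full", bg, 3)$arborization_area_mm2
  a2 <- region_axon_metrics(gi2, "full", bg, 3)$arborization_area_mm2
  expect_equal(a2, a1 / 4)
})

test_that("labeled_image validates masks and pixel size", {
  px <- matrix(1, 4, 4)
  expect_error(labeled_image(px, 0), "pixel_size_mm")
  expect_error(labeled_image(matrix(-1, 2, 2), 1), "nonnegative")
  expect_error(labeled_image(px, 1, rois = list(r = matrix(TRUE, 2, 2))),
               "shape")
  overlap <- matrix(TRUE, 4, 4)
  expect_error(labeled_image(px, 1, cell_masks = list(overlap, overlap)),
               "disjoint")
})
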