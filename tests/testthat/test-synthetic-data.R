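test_that("generators are deterministic given (config, seed)", {
  cfg <- synth_config(n_cells = 60, image_size = 64, blobs_per_image = 3,
                      axon_area_px = 50)
  expect_identical(gen_point_pattern(cfg, seed = 7),
                   gen_point_pattern(cfg, seed = 7))
  expect_identical(gen_tracing_counts(cfg, seed = 7),
                   gen_tracing_counts(cfg, seed = 7))
  expect_identical(gen_section_image(cfg, seed = 7)$pixels,
                   gen_section_image(cfg, seed = 7)$pixels)
  t1 <- gen_photometry(cfg, events = 10, seed = 7, duration_s = 30)
  t2 <- gen_photometry(cfg, events = 10, seed = 7, duration_s = 30)
  expect_identical(t1$f470, t2$f470)
  # different seeds differ
  expect_false(identical(gen_point_pattern(cfg, seed = 7)$x_mm,
                         gen_point_pattern(cfg, seed = 8)$x_mm))
})

test_that("per-mouse substreams are stable when mice are added", {
  cfg2 <- unbiased_config(n_cells = 40, n_mice_per_group = 2)
  cfg3 <- unbiased_config(n_cells = 40, n_mice_per_group = 3)
  a <- gen_cell_tables(cfg2, seed = 5)
  b <- gen_cell_tables(cfg3, seed = 5)
  keys_a <- paste(a$group, a$mouse_id)
  bsub <- b[paste(b$group, b$mouse_id) %in% unique(keys_a), ]
  expect_identical(a$x_mm[order(keys_a)],
                   bsub$x_mm[order(paste(bsub$group, bsub$mouse_id))])
})

test_that("poisson pattern is uniform over DV thirds; gradient enriches ventrally", {
  cfg <- synth_config(n_cells = 3000, ventral_gradient = 0)
  cells <- gen_point_pattern(cfg, seed = 11)
  thirds <- table(cut(cells$y_mm, c(0, 1 / 3, 2 / 3, 1)))
  # 3-sigma binomial tolerance around n/3
  tol <- 3 * sqrt(3000 * (1 / 3) * (2 / 3))
  expect_true(all(abs(thirds - 1000) < tol))

  g <- 25
  cg <- synth_config(n_cells = 3000, ventral_gradient = g)
  cellsg <- gen_point_pattern(cg, seed = 11)
  emp <- mean(cellsg$y_mm < 0.5)
  # analytic ventral-half mass of the exponential density on [0, 1]
  anal <- (1 - exp(-g * 0.5)) / (1 - exp(-g))
  expect_gt(emp, 0.8)
  expect_lt(abs(emp - anal), 3 * sqrt(anal * (1 - anal) / 3000))
})

test_that("thomas clustering shrinks within-section pairwise distances", {
  meds <- vapply(1:15, function(s) {
    ct <- gen_point_pattern(synth_config(n_cells = 120, pattern = "thomas",
                                         cluster_sd = 0.02), seed = s)
    cp <- gen_point_pattern(synth_config(n_cells = 120), seed = s + 1000)
    c(oracle_within_section_median(ct), oracle_within_section_median(cp))
  }, numeric(2))
  # systematic effect: clear per-seed majority and a smaller pooled median
  expect_gte(mean(meds[1, ] < meds[2, ]), 0.75)
  expect_lt(median(meds[1, ]), median(meds[2, ]))
})

test_that("smaller cluster_sd gives stochastically smaller pair distances", {
  m_small <- vapply(1:10, function(s)
    oracle_within_section_median(
      gen_point_pattern(synth_config(n_cells = 120, pattern = "thomas",
                                     cluster_sd = 0.01), seed = s)),
    numeric(1))
  m_large <- vapply(1:10, function(s)
    oracle_within_section_median(
      gen_point_pattern(synth_config(n_cells = 120, pattern = "thomas",
                                     cluster_sd = 0.1), seed = s)),
    numeric(1))
  expect_lt(median(m_small), median(m_large))
})

test_that("point-pattern geometry and config errors are rejected", {
  expect_error(synth_config(n_cells = -1), "n_cells")
  expect_error(synth_config(pattern = "thomas", cluster_sd = 0),
               "cluster_rate > 0 and cluster_sd > 0")
  cfg <- synth_config()
  cfg$region_extent$dv <- c(0.5, 0.5)
  class(cfg) <- "synth_config"
  expect_error(gen_point_pattern(cfg, seed = 1), "zero volume")
})

test_that("tracing counts follow the multinomial expectation", {
  w <- stats::setNames(rep(1, 4), c("A", "B", "C", "D"))
  cfg <- synth_config(region_names = names(w),
                      group_region_weights = list(g1 = w),
                      counts_per_mouse = 4000, n_mice_per_group = 8)
  counts <- gen_tracing_counts(cfg, seed = 3)
  fr <- colMeans(as.matrix(counts[, attr(counts, "regions")]) / 4000)
  tol <- 3 * sqrt(0.25 * 0.75 / 4000) / sqrt(8)
  expect_true(all(abs(fr - 0.25) < 3 * sqrt(0.25 * 0.75 / 4000)))

  # doubled weight: mean fraction ratio matches the normalized weights
  w2 <- w; w2["A"] <- 2
  cfg2 <- synth_config(region_names = names(w),
                       group_region_weights = list(g1 = w, g2 = w2),
                       counts_per_mouse = 4000, n_mice_per_group = 10)
  c2 <- gen_tracing_counts(cfg2, seed = 3)
  m <- as.matrix(c2[, attr(c2, "regions")]) / 4000
  fA <- tapply(m[, "A"], c2$group, mean)
  expect_equal(unname(fA["g2"] / fA["g1"]), (2 / 5) / (1 / 4),
               tolerance = 0.05)
})

test_that("degenerate and invalid count configurations are handled", {
  cfg <- synth_config(counts_per_mouse = 0, n_mice_per_group = 2)
  counts <- gen_tracing_counts(cfg, seed = 1)
  expect_true(all(as.matrix(counts[, attr(counts, "regions")]) == 0))
  expect_true(attr(counts, "degenerate"))
  expect_error(synth_config(region_names = character(0)), "region_names")
})

test_that("section images plant exact, recoverable ground truth", {
  cfg0 <- synth_config(image_size = 64, blobs_per_image = 0)
  img0 <- gen_section_image(cfg0, seed = 1)
  expect_equal(attr(img0, "truth")$n_blobs, 0)
  expect_equal(nrow(attr(img0, "truth")$centroids), 0)

  cfgc <- synth_config(image_size = 64, blobs_per_image = 2,
                       background_sd = 0)
  imgc <- gen_section_image(cfgc, seed = 2)
  bgpx <- imgc$pixels[imgc$rois$background]
  expect_true(all(bgpx == bgpx[1]))   # exactly constant background

  cfga <- synth_config(image_size = 128, blobs_per_image = 0,
                       axon_area_px = 500)
  imga <- gen_section_image(cfga, seed = 3)
  expect_equal(attr(imga, "truth")$axon_area_px, 500)
  bg <- estimate_background(imga)
  expect_equal(sum(threshold_mask(imga, bg, 3)), 500)

  # unplaceable blob request fails explicitly
  cfgbad <- synth_config(image_size = 48, blobs_per_image = 50)
  expect_error(gen_section_image(cfgbad, seed = 1), "non-overlapping")
})

test_that("photometry generator matches its closed-form transient", {
  cfg <- synth_config(photometry_noise_sd = 0)
  tr <- gen_photometry(cfg, events = c(20, 80), seed = 1, duration_s = 120)
  ep <- dff(tr, baseline_s = 2, window_s = c(-2, 10),
            variant = "conventional")
  expect_equal(nrow(ep), 2)
  # amplitude = 0 gives a flat dF/F
  cfg0 <- synth_config(photometry_noise_sd = 0, transient_amplitude = 0)
  tr0 <- gen_photometry(cfg0, events = 20, seed = 1, duration_s = 60)
  expect_true(all(abs(dff(tr0, 2, c(-2, 10))) < 1e-12))
  # noiseless AUC over [0, 5*tau] equals A*tau*(1 - e^-5)
  A <- cfg$transient_amplitude; tau <- cfg$transient_tau_s
  a <- epoch_auc(ep, window_s = c(0, 5 * tau))
  expect_equal(a$per_event[1], A * tau * (1 - exp(-5)), tolerance = 1e-4)
  expect_error(gen_photometry(cfg, events = 500, seed = 1, duration_s = 100),
               "outside")
})
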