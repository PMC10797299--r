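test_that("ap_profile computes density and normalized fractions", {
  # 10 cells on one 2 mm^2 section, none elsewhere
  cells <- make_cells(-3.5, x_mm = runif(10), y_mm = runif(10), area = 2)
  ap <- ap_profile(cells)
  row <- ap[ap$n > 0, ]
  expect_equal(nrow(row), 1)
  expect_equal(row$density_per_mm2, 5)
  expect_equal(row$fraction, 1.0)

  # equal counts in 8 bins -> fraction 0.125 each
  cells8 <- do.call(rbind, lapply(seq(-3.8, -3.1, by = 0.1), function(ap0)
    make_cells(ap0, x_mm = runif(3), y_mm = runif(3))))
  class(cells8) <- c("section_cell_table", "data.frame")
  ap8 <- ap_profile(cells8)
  expect_equal(ap8$fraction[ap8$n > 0], rep(0.125, 8))
})

test_that("ap and ml profiles agree with brute-force tallying", {
  cells <- gen_cell_tables(unbiased_config(n_cells = 150,
                                           n_mice_per_group = 2), seed = 9)
  ap <- ap_profile(cells)
  oracle <- oracle_ap_fractions(cells)
  for (i in which(ap$n > 0))
    expect_equal(ap$fraction[i],
                 oracle[[paste(ap$mouse_id[i], ap$ap_bin_mm[i])]])
  # fractions sum to 1 per mouse
  sums <- tapply(ap$fraction, ap$mouse_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  ml <- ml_profile(cells)
  edges <- c(0, 0.3, 0.6, Inf)
  oml <- oracle_ml_percent(cells, edges)
  for (i in seq_len(nrow(ml)))
    expect_equal(ml$percent[i],
                 oml[[paste(ml$mouse_id[i], ml$section_ap_mm[i],
                            match(ml$ml_bin[i], unique(ml$ml_bin)))]])
  psum <- tapply(ml$percent, paste(ml$mouse_id, ml$section_ap_mm), sum)
  expect_true(all(abs(psum - 100) < 1e-9))
})

test_that("ml_profile handles the trivial binnings", {
  cells <- make_cells(-3.4, x_mm = rep(0.1, 5), y_mm = runif(5))
  ml <- ml_profile(cells)
  expect_equal(ml$percent[ml$ml_bin == "0~0.3"], 100)
  cells3 <- make_cells(-3.4, x_mm = c(0.1, 0.4, 0.7), y_mm = runif(3))
  expect_equal(ml_profile(cells3)$percent, rep(100 / 3, 3))
})

test_that("landmark distances are signed offsets from the section bottom", {
  cells <- make_cells(-3.5, x_mm = 0.2, y_mm = 1.2)
  d <- landmark_distance(cells, landmark_y = 1.0)
  expect_equal(d$values_mm, 0.2)
  # all cells on the landmark: degenerate CDF step at 0
  cells0 <- make_cells(-3.5, x_mm = runif(4), y_mm = rep(1, 4))
  d0 <- landmark_distance(cells0, landmark_y = 1.0)
  expect_true(all(d0$values_mm == 0))
  expect_equal(d0$ecdf(0), 1)
  # below-landmark cells are flagged but kept, signed
  expect_message(
    dn <- landmark_distance(make_cells(-3.5, 0, y_mm = 0.5),
                            landmark_y = 1.0), "below the landmark")
  expect_equal(dn$values_mm, -0.5)
  # default window excludes sections outside [-3.6, -3.3)
  far <- make_cells(-3.0, x_mm = 0.1, y_mm = 0.5)
  expect_error(landmark_distance(far), "no cells in the AP window")
})

test_that("ventral-gradient cells sit below the uniform pattern's CDF", {
  cg <- gen_point_pattern(synth_config(n_cells = 800, ventral_gradient = 10),
                          seed = 4)
  cu <- gen_point_pattern(synth_config(n_cells = 800), seed = 5)
  dg <- landmark_distance(cg, ap_window_mm = c(-3.8, -3.0))
  du <- landmark_distance(cu, ap_window_mm = c(-3.8, -3.0))
  grid <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(dg$ecdf(grid) >= du$ecdf(grid)))
})

test_that("paired distances honor geometry, exhaustion and exchangeability", {
  tri <- make_cells(-3.5, x_mm = c(0, 3), y_mm = c(0, 4))
  expect_equal(paired_distances(tri, n_pairs = 1, seed = 1)$values_mm, 5)

  three <- make_cells(-3.5, x_mm = c(0, 1, 2), y_mm = c(0, 0, 0))
  expect_message(s3 <- paired_distances(three, n_pairs = 10, seed = 1),
                 "only 3 distinct pairs")
  expect_equal(s3$n, 3)
  expect_equal(sort(s3$values_mm), c(1, 1, 2))

  # row permutation changes nothing for a fixed seed
  cells <- gen_point_pattern(synth_config(n_cells = 200), seed = 2)
  perm <- cells[sample(nrow(cells)), ]
  class(perm) <- c("section_cell_table", "data.frame")
  a <- paired_distances(cells, n_pairs = 150, seed = 10)
  b <- paired_distances(perm, n_pairs = 150, seed = 10)
  expect_equal(sort(a$values_mm), sort(b$values_mm))

  # pairs never straddle sections
  two <- rbind(make_cells(-3.5, x_mm = c(0, 0.001), y_mm = c(0, 0)),
               make_cells(-3.2, x_mm = c(5, 5.001), y_mm = c(0, 0)))
  class(two) <- c("section_cell_table", "data.frame")
  s <- paired_distances(two, n_pairs = 2, seed = 1)
  expect_true(all(s$values_mm < 1))

  one <- make_cells(-3.5, x_mm = 0, y_mm = 0)
  expect_error(paired_distances(one), "at least 2 cells")
})

test_that("KS comparison equals the brute-force sup ECDF difference", {
  same <- runif(30)
  expect_equal(ecdf_compare(same, same)$D, 0)
  expect_equal(ecdf_compare(rep(0, 10), rep(1, 10))$D, 1)
  set.seed(77)
  for (i in 1:5) {
    a <- round(rexp(20), 2)
    b <- round(rexp(25, 0.7), 2)
    expect_equal(ecdf_compare(a, b)$D, oracle_ks_D(a, b))
  }
  expect_error(ecdf_compare(numeric(0), 1:3), "non-empty")
})

test_that("colocalization fractions count marker intersections", {
  mk <- c(rep("cFos;EGFP;TH", 5), rep("cFos;EGFP", 5), rep("cFos;TH", 3))
  cells <- make_cells(-3.5, x_mm = seq_along(mk) / 10,
                      y_mm = rep(0.5, length(mk)))
  cells$markers <- mk
  expect_equal(colocalization_fraction(cells, "EGFP", "TH"), 0.5)
  expect_equal(colocalization_fraction(cells, "EGFP", "EGFP"), 1.0)
  expect_true(is.na(colocalization_fraction(cells, "GABA", "TH")))
  # against brute-force set intersection on generated flags
  gc <- gen_point_pattern(synth_config(n_cells = 300), seed = 6)
  flags <- strsplit(gc$markers, ";")
  base <- vapply(flags, function(f) "EGFP" %in% f, logical(1))
  co <- vapply(flags, function(f) "TH" %in% f, logical(1))
  expect_equal(colocalization_fraction(gc, "EGFP", "TH"),
               sum(base & co) / sum(base))
  byap <- colocalization_fraction(gc, "EGFP", "TH", by = "ap")
  expect_true(all(byap$n_both <= byap$n_base))
})
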