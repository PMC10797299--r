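# Independent brute-force oracles. These deliberately share no code with
# the implementation: plain loops and first-principles formulas only.

# per-mouse AP-bin fractions by naive tallying
oracle_ap_fractions <- function(cells, bin_mm = 0.1) {
  out <- list()
  for (m in unique(cells$mouse_id)) {
    sub <- cells[cells$mouse_id == m, ]
    bins <- round(floor(round(sub$section_ap_mm / bin_mm, 9)) * bin_mm, 9)
    for (b in unique(bins)) {
      out[[paste(m, b)]] <- sum(bins == b) / nrow(sub)
    }
  }
  out
}

# per-section ML-bin percentages by naive tallying
oracle_ml_percent <- function(cells, edges) {
  out <- list()
  key <- paste(cells$mouse_id, cells$section_ap_mm)
  for (k in unique(key)) {
    sub <- cells[key == k, ]
    for (i in seq_len(length(edges) - 1)) {
      n <- 0
      for (x in abs(sub$x_mm))
        if (x >= edges[i] && x < edges[i + 1]) n <- n + 1
      out[[paste(k, i)]] <- 100 * n / nrow(sub)
    }
  }
  out
}

# two-sample KS statistic as the sup ECDF difference over pooled values
oracle_ks_D <- function(a, b) {
  pool <- sort(unique(c(a, b)))
  dmax <- 0
  for (v in pool) {
    fa <- sum(a <= v) / length(a)
    fb <- sum(b <= v) / length(b)
    dmax <- max(dmax, abs(fa - fb))
  }
  dmax
}

# region axon metrics by an explicit per-pixel double loop
oracle_region_metrics <- function(pixels, roimask, background, k, psz) {
  area_px <- 0; dens <- 0; roi_px <- 0
  for (i in seq_len(nrow(pixels))) {
    for (j in seq_len(ncol(pixels))) {
      if (roimask[i, j]) {
        roi_px <- roi_px + 1
        if (pixels[i, j] > k * background) {
          area_px <- area_px + 1
          dens <- dens + pixels[i, j]
        }
      }
    }
  }
  list(arborization_area_mm2 = area_px * psz^2,
       integrated_density = dens,
       roi_area_mm2 = roi_px * psz^2)
}

# per-cell integrated density by an explicit per-pixel loop
oracle_percell <- function(pixels, masks, background, k) {
  vapply(masks, function(m) {
    s <- 0
    for (i in seq_len(nrow(pixels)))
      for (j in seq_len(ncol(pixels)))
        if (m[i, j] && pixels[i, j] > k * background)
          s <- s + pixels[i, j]
    s
  }, numeric(1))
}

# depth-1 exhaustive-split Gini decrease per feature (two classes)
oracle_single_split_gini <- function(x, y) {
  y <- as.integer(factor(y))
  n <- length(y)
  gini <- function(idx) {
    if (length(idx) == 0) return(0)
    p <- mean(y[idx] == 1)
    2 * p * (1 - p)
  }
  root <- gini(seq_len(n))
  apply(x, 2, function(v) {
    cuts <- sort(unique(v))
    if (length(cuts) < 2) return(0)
    mids <- (head(cuts, -1) + tail(cuts, -1)) / 2
    best <- 0
    for (c0 in mids) {
      l <- which(v <= c0); r <- which(v > c0)
      dec <- root - (length(l) / n) * gini(l) - (length(r) / n) * gini(r)
      best <- max(best, dec)
    }
    best
  })
}

# median within-section pairwise distance by full enumeration
oracle_within_section_median <- function(cells) {
  key <- paste(cells$mouse_id, cells$section_ap_mm)
  d <- c()
  for (k in unique(key)) {
    sub <- cells[key == k, ]
    n <- nrow(sub)
    if (n < 2) next
    for (i in seq_len(n - 1))
      for (j in (i + 1):n)
        d <- c(d, sqrt((sub$x_mm[i] - sub$x_mm[j])^2 +
                       (sub$y_mm[i] - sub$y_mm[j])^2))
  }
  stats::median(d)
}

# trapezoid integral from first principles
oracle_trapz <- function(t, y) {
  s <- 0
  for (i in seq_len(length(t) - 1))
    s <- s + (t[i + 1] - t[i]) * (y[i] + y[i + 1]) / 2
  s
}
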