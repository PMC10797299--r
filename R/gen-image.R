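#' Simulate a grayscale section image with known ground truth
#'
#' Builds a synthetic confocal-like section: Gaussian background noise
#' (clipped at zero, rounded to integer gray levels), non-overlapping
#' isotropic Gaussian cell blobs at recorded centroids, and optionally an
#' axon texture of an exact pixel area drawn as a random walk. The image is
#' partitioned into named ROIs: a signal-free `background` strip, a `cells`
#' zone holding the blobs, an `axon` zone holding the texture (when
#' requested), and `full`.
#'
#' @param config a [synth_config()].
#' @param seed RNG seed.
#' @param n_blobs number of cell blobs (default `config$blobs_per_image`).
#' @param axon_area_px exact axon pixel area (default `config$axon_area_px`).
#' @return A [labeled_image()] whose `attr(, "truth")` records the blob
#'   centroids (pixels and mm), the per-cell planted integrated intensity
#'   (sum of final pixel values over each blob's footprint), the axon mask
#'   and its exact area, and the generator parameters.
#' @examples
#' cfg <- synth_config(image_size = 64, blobs_per_image = 3)
#' img <- gen_section_image(cfg, seed = 1)
#' attr(img, "truth")$n_blobs
#' @export
gen_section_image <- function(config, seed = config$seed,
                              n_blobs = config$blobs_per_image,
                              axon_area_px = config$axon_area_px) {
  stopifnot(inherits(config, "synth_config"))
  sz <- config$image_size
  if (sz <= 0) stop("image_size must be positive", call. = FALSE)
  r <- config$cell_radius_px
  sigma <- r / 2
  kw <- max(1L, ceiling(3 * sigma))        # kernel half-width
  bw <- max(4L, sz %/% 16L)                # background strip width
  have_axon <- axon_area_px > 0
  cells_hi <- if (have_axon) floor(sz * 0.6) else sz
  axon_lo <- floor(sz * 0.65)

  rois <- list(
    full = matrix(TRUE, sz, sz),
    background = col_roi(sz, 1L, bw),
    cells = col_roi(sz, bw + 1L, cells_hi)
  )
  if (have_axon) rois$axon <- col_roi(sz, axon_lo, sz)

  res <- with_seed(seed, {
    img <- matrix(pmax(0, stats::rnorm(sz * sz, config$background_mean,
                                       config$background_sd)), sz, sz)

    # --- plant non-overlapping Gaussian blobs in the cells zone ---
    lo_r <- kw + 1L; hi_r <- sz - kw
    lo_c <- bw + kw + 1L; hi_c <- cells_hi - kw
    centers <- matrix(numeric(0), 0, 2)
    if (n_blobs > 0) {
      if (hi_r < lo_r || hi_c < lo_c)
        stop("cells zone too small for the requested blob radius",
             call. = FALSE)
      min_sep <- 5 * r
      # sequential rejection can paint itself into a corner in tight
      # geometries; restart from scratch a bounded number of times
      for (restart in 1:25) {
        centers <- matrix(numeric(0), 0, 2)
        tries <- 0L
        while (nrow(centers) < n_blobs && tries <= 200L * n_blobs) {
          tries <- tries + 1L
          cand <- c(sample(lo_r:hi_r, 1), sample(lo_c:hi_c, 1))
          if (nrow(centers) == 0 ||
              all(sqrt((centers[, 1] - cand[1])^2 +
                       (centers[, 2] - cand[2])^2) >= min_sep))
            centers <- rbind(centers, cand)
        }
        if (nrow(centers) == n_blobs) break
      }
      if (nrow(centers) < n_blobs)
        stop(sprintf(
          "could not place %d non-overlapping blobs after bounded retries",
          n_blobs), call. = FALSE)
    }
    contrib <- vector("list", nrow(centers))
    for (i in seq_len(nrow(centers))) {
      rr <- (centers[i, 1] - kw):(centers[i, 1] + kw)
      cc <- (centers[i, 2] - kw):(centers[i, 2] + kw)
      d2 <- outer((rr - centers[i, 1])^2, (cc - centers[i, 2])^2, "+")
      add <- config$signal_amplitude * exp(-d2 / (2 * sigma^2))
      img[rr, cc] <- img[rr, cc] + add
      contrib[[i]] <- list(rows = rr, cols = cc, add = add)
    }

    # --- axon texture: exact-area random walk in the axon zone ---
    axon_mask <- matrix(FALSE, sz, sz)
    if (have_axon) {
      if (axon_area_px > (sz - axon_lo + 1L) * sz)
        stop("axon_area_px exceeds the axon zone", call. = FALSE)
      pos <- c(sample(1:sz, 1), sample(axon_lo:sz, 1))
      axon_mask[pos[1], pos[2]] <- TRUE
      placed <- 1L
      steps <- 0L
      while (placed < axon_area_px) {
        steps <- steps + 1L
        if (steps > 500L * axon_area_px)
          stop("could not draw the requested axon area", call. = FALSE)
        stp <- switch(sample.int(4L, 1), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
        cand <- pos + stp
        if (cand[1] < 1 || cand[1] > sz || cand[2] < axon_lo || cand[2] > sz) {
          # restart from a visited pixel to keep the walk inside the zone
          vis <- which(axon_mask, arr.ind = TRUE)
          pos <- vis[sample.int(nrow(vis), 1), ]
          next
        }
        pos <- cand
        if (!axon_mask[pos[1], pos[2]]) {
          axon_mask[pos[1], pos[2]] <- TRUE
          placed <- placed + 1L
        }
      }
      img[axon_mask] <- img[axon_mask] + config$signal_amplitude
    }
    list(img = round(img), centers = centers, contrib = contrib,
         axon_mask = axon_mask)
  })

  # per-cell masks: discs of radius 2r around each centroid (covers the
  # 3-sigma blob footprint), pairwise disjoint by the 5r separation rule
  cell_masks <- lapply(seq_len(nrow(res$centers)), function(i) {
    disc_mask(sz, res$centers[i, 1], res$centers[i, 2], 2 * r)
  })
  cell_intensity <- vapply(seq_len(nrow(res$centers)), function(i) {
    ct <- res$contrib[[i]]
    foot <- ct$add >= 0.5
    sum(res$img[ct$rows, ct$cols][foot])
  }, numeric(1))

  centroids <- if (nrow(res$centers)) {
    data.frame(row = res$centers[, 1], col = res$centers[, 2],
               x_mm = (res$centers[, 2] - 0.5) * config$pixel_size_mm,
               y_mm = (res$centers[, 1] - 0.5) * config$pixel_size_mm)
  } else {
    data.frame(row = numeric(0), col = numeric(0),
               x_mm = numeric(0), y_mm = numeric(0))
  }

  img <- labeled_image(res$img, config$pixel_size_mm, rois = rois,
                       cell_masks = cell_masks)
  attr(img, "truth") <- list(
    n_blobs = nrow(res$centers), centroids = centroids,
    cell_intensity = cell_intensity,
    axon_mask = res$axon_mask, axon_area_px = sum(res$axon_mask),
    background_mean = config$background_mean,
    signal_amplitude = config$signal_amplitude, seed = seed)
  img
}

col_roi <- function(sz, from, to) {
  m <- matrix(FALSE, sz, sz)
  if (to >= from) m[, from:to] <- TRUE
  m
}

disc_mask <- function(sz, row, col, radius) {
  rr <- matrix(seq_len(sz), sz, sz)
  cc <- matrix(seq_len(sz), sz, sz, byrow = TRUE)
  (rr - row)^2 + (cc - col)^2 <= radius^2
}
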