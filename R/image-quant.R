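#' Construct a labeled grayscale image
#'
#' A 2D nonnegative grayscale raster with a physical pixel size, named ROI
#' masks and optional per-cell outline masks — the container every
#' image-quantification operator works on.
#'
#' @param pixels numeric matrix of nonnegative gray values.
#' @param pixel_size_mm physical pixel size, mm/pixel.
#' @param rois named list of logical masks, same shape as `pixels`.
#' @param cell_masks optional list of pairwise-disjoint logical masks, one
#'   per cell.
#' @return An object of class `labeled_image`.
#' @export
labeled_image <- function(pixels, pixel_size_mm, rois = list(),
                          cell_masks = NULL) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (any(pixels < 0)) stop("pixels must be nonnegative", call. = FALSE)
  if (!is.numeric(pixel_size_mm) || pixel_size_mm <= 0)
    stop("pixel_size_mm must be positive", call. = FALSE)
  for (nm in names(rois)) {
    m <- rois[[nm]]
    if (!is.logical(m) || !identical(dim(m), dim(pixels)))
      stop(sprintf("ROI '%s' must be a logical mask matching the image shape",
                   nm), call. = FALSE)
  }
  if (!is.null(cell_masks)) {
    cov <- matrix(0L, nrow(pixels), ncol(pixels))
    for (i in seq_along(cell_masks)) {
      m <- cell_masks[[i]]
      if (!is.logical(m) || !identical(dim(m), dim(pixels)))
        stop("cell masks must be logical and match the image shape",
             call. = FALSE)
      cov <- cov + m
    }
    if (any(cov > 1L))
      stop("cell masks must be pairwise disjoint", call. = FALSE)
  }
  structure(list(pixels = pixels, pixel_size_mm = pixel_size_mm,
                 rois = rois, cell_masks = cell_masks),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  cat(sprintf("Labeled image: %d x %d px @ %g mm/px, %d ROI(s), %d cell mask(s)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_mm,
              length(x$rois), length(x$cell_masks %||% list())))
  invisible(x)
}

resolve_roi <- function(image, roi) {
  if (is.character(roi)) {
    if (!roi %in% names(image$rois))
      stop(sprintf("unknown ROI '%s'", roi), call. = FALSE)
    image$rois[[roi]]
  } else if (is.logical(roi) && identical(dim(roi), dim(image$pixels))) {
    roi
  } else stop("roi must be a name or a logical mask", call. = FALSE)
}

#' Estimate the image background level
#'
#' The median gray value of a designated signal-free region. The median is
#' used because it resists contamination by stray bright pixels.
#'
#' @param image a [labeled_image()].
#' @param roi ROI name or logical mask delimiting the background region.
#' @return A single gray value.
#' @export
estimate_background <- function(image, roi = "background") {
  m <- resolve_roi(image, roi)
  if (!any(m)) stop("background region is empty", call. = FALSE)
  stats::median(image$pixels[m])
}

#' Background-relative threshold mask
#'
#' Pixels strictly greater than `k` times the background gray value are
#' interpreted as signal: `k = 3` is the convention for axonal signal,
#' `k = 1.5` for PLA puncta.
#'
#' @param image a [labeled_image()].
#' @param background background gray value (see [estimate_background()]).
#' @param k threshold multiplier (> 0).
#' @return Logical mask of supra-threshold pixels.
#' @examples
#' img <- labeled_image(matrix(c(10, 30, 30.5, 61), 2), 0.01)
#' threshold_mask(img, background = 10, k = 3)
#' @export
threshold_mask <- function(image, background, k = 3) {
  stopifnot(background >= 0, k > 0)
  image$pixels > k * background
}

# 8-connected component labeling by iterative minimum-label propagation.
label_components <- function(mask) {
  stopifnot(is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(lab)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  big <- sum(mask) + 1L
  repeat {
    cur <- ifelse(mask, lab, big)
    best <- cur
    for (s in shifts) {
      nb <- matrix(big, nr, nc)
      rs <- max(1, 1 + s[1]):min(nr, nr + s[1])
      cs <- max(1, 1 + s[2]):min(nc, nc + s[2])
      nb[rs, cs] <- cur[rs - s[1], cs - s[2]]
      best <- pmin(best, nb)
    }
    best[!mask] <- 0L
    best[mask & best == big] <- lab[mask & best == big]
    if (identical(best, lab)) break
    lab <- best
  }
  lab[mask] <- match(lab[mask], sort(unique(lab[mask])))
  lab
}

#' Count cells as connected components of a binary mask
#'
#' Cells are 8-connected components of the mask with at least
#' `min_area_px` pixels; touching cells count as one component (no
#' watershed splitting is attempted).
#'
#' @param mask logical matrix (e.g. from [threshold_mask()]).
#' @param min_area_px minimum component area, pixels.
#' @param pixel_size_mm optional pixel size for centroids in mm.
#' @return list with `count`, `centroids` (data.frame `row`, `col`,
#'   `area_px`, and `x_mm`/`y_mm` when a pixel size is given), and the
#'   component `labels` matrix.
#' @export
count_cells <- function(mask, min_area_px = 1L, pixel_size_mm = NULL) {
  stopifnot(is.logical(mask))
  lab <- label_components(mask)
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  areas <- tabulate(lab[lab > 0], nbins = max(c(0L, ids)))
  keep <- ids[areas[ids] >= min_area_px]
  cent <- do.call(rbind, lapply(keep, function(i) {
    w <- which(lab == i, arr.ind = TRUE)
    c(row = mean(w[, 1]), col = mean(w[, 2]), area_px = nrow(w))
  }))
  cent <- if (is.null(cent))
    data.frame(row = numeric(0), col = numeric(0), area_px = numeric(0))
  else as.data.frame(cent)
  if (!is.null(pixel_size_mm)) {
    cent$x_mm <- (cent$col - 0.5) * pixel_size_mm
    cent$y_mm <- (cent$row - 0.5) * pixel_size_mm
  }
  list(count = length(keep), centroids = cent, labels = lab)
}

#' Axonal signal metrics for one region
#'
#' Applies the background-relative threshold within a named ROI and
#' reports the arborization area (supra-threshold pixel count times the
#' pixel area) and the integrated density (sum of gray values over the
#' supra-threshold pixels in the ROI).
#'
#' @param image a [labeled_image()].
#' @param roi ROI name.
#' @param background background gray value.
#' @param k threshold multiplier (default 3, the axonal-signal rule).
#' @return One-row data.frame: `roi`, `arborization_area_mm2`,
#'   `integrated_density`, `roi_area_mm2`, `background`, `k`.
#' @export
region_axon_metrics <- function(image, roi, background, k = 3) {
  m <- resolve_roi(image, roi)
  if (!any(m)) stop("ROI is disjoint from the image", call. = FALSE)
  sig <- threshold_mask(image, background, k) & m
  psz2 <- image$pixel_size_mm^2
  data.frame(roi = if (is.character(roi)) roi else "mask",
             arborization_area_mm2 = sum(sig) * psz2,
             integrated_density = sum(image$pixels[sig]),
             roi_area_mm2 = sum(m) * psz2,
             background = background, k = k,
             stringsAsFactors = FALSE)
}

#' Per-cell integrated signal intensity
#'
#' For each cell outline mask, the sum of gray values over the pixels in
#' the mask that exceed `k` times background — the per-cell integrated
#' density used for PLA puncta quantification (default `k = 1.5`).
#'
#' @param image a [labeled_image()] with `cell_masks`.
#' @param background background gray value.
#' @param k threshold multiplier.
#' @return Numeric vector, one integrated density per cell mask.
#' @export
percell_intensity <- function(image, background, k = 1.5) {
  if (is.null(image$cell_masks) || length(image$cell_masks) == 0)
    stop("image has no cell masks", call. = FALSE)
  thr <- threshold_mask(image, background, k)
  vapply(image$cell_masks, function(m) sum(image$pixels[m & thr]),
         numeric(1))
}
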