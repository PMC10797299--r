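#' Anterior-posterior profile of labeled cells
#'
#' Bins cells into half-open AP slabs `[lo, hi)` and reports, per mouse and
#' bin, the cell count, the areal density (count divided by the summed area
#' of the sections contributing cells to that bin), and the fraction of the
#' mouse's total cell count. Fractions over bins sum to 1 per mouse; a
#' mouse with zero cells would have undefined fractions and is reported as
#' missing, not zero.
#'
#' @param cells a `section_cell_table` (see [gen_point_pattern()] or
#'   [read_cell_table()]).
#' @param bin_mm AP bin width, mm (default 0.1, one coronal slab).
#' @param ap_range optional numeric length-2 atlas range; defaults to the
#'   bin-aligned span of the data.
#' @return data.frame with columns `mouse_id`, `group`, `ap_bin_mm`
#'   (lower edge), `n`, `density_per_mm2`, `fraction`.
#' @examples
#' cells <- gen_point_pattern(synth_config(n_cells = 50), seed = 1)
#' ap <- ap_profile(cells)
#' sum(ap$fraction)
#' @export
ap_profile <- function(cells, bin_mm = 0.1, ap_range = NULL) {
  stopifnot(is.data.frame(cells), nrow(cells) > 0)
  if (any(cells$section_area_mm2 <= 0))
    stop("every contributing section needs a positive area", call. = FALSE)
  if (is.null(ap_range)) {
    lo <- floor(min(cells$section_ap_mm) / bin_mm) * bin_mm
    hi <- ceiling((max(cells$section_ap_mm) + 1e-9) / bin_mm) * bin_mm
  } else {
    lo <- ap_range[1]; hi <- ap_range[2]
  }
  edges <- round(seq(lo, hi, by = bin_mm), 9)
  if (edges[length(edges)] <= max(cells$section_ap_mm))
    edges <- c(edges, round(edges[length(edges)] + bin_mm, 9))
  bin <- edges[findInterval(cells$section_ap_mm, edges,
                            rightmost.closed = FALSE)]
  out <- do.call(rbind, lapply(split(seq_len(nrow(cells)), cells$mouse_id),
                               function(idx) {
    m <- cells[idx, , drop = FALSE]
    mb <- bin[idx]
    total <- nrow(m)
    grid <- edges[-length(edges)]
    n <- vapply(grid, function(b) sum(mb == b), numeric(1))
    area <- vapply(grid, function(b) {
      s <- m[mb == b, , drop = FALSE]
      if (nrow(s) == 0) return(NA_real_)
      sum(tapply(s$section_area_mm2, s$section_ap_mm, function(a) a[1]))
    }, numeric(1))
    data.frame(mouse_id = m$mouse_id[1], group = m$group[1],
               ap_bin_mm = grid, n = n,
               density_per_mm2 = n / area,
               fraction = if (total > 0) n / total else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Mediolateral profile of labeled cells per section
#'
#' Bins `|x_mm|` (distance from the midline) into the given edges and
#' reports, per section, the percentage of that section's cells in each
#' bin; per-section percentages sum to 100.
#'
#' @param cells a `section_cell_table`.
#' @param edges_mm increasing bin edges over `|x|`; the last edge may be
#'   `Inf` (default `c(0, 0.3, 0.6, Inf)`, the conventional one-sided ML
#'   bins).
#' @return data.frame with columns `mouse_id`, `group`, `section_ap_mm`,
#'   `ml_bin`, `n`, `percent`.
#' @export
ml_profile <- function(cells, edges_mm = c(0, 0.3, 0.6, Inf)) {
  stopifnot(is.data.frame(cells), nrow(cells) > 0)
  ax <- abs(cells$x_mm)
  if (any(!is.finite(ax))) stop("|x_mm| must be finite", call. = FALSE)
  nb <- length(edges_mm) - 1L
  labs <- vapply(seq_len(nb), function(i) {
    if (is.infinite(edges_mm[i + 1])) sprintf("%g~", edges_mm[i])
    else sprintf("%g~%g", edges_mm[i], edges_mm[i + 1])
  }, character(1))
  bin <- findInterval(ax, edges_mm, rightmost.closed = FALSE)
  bin[bin < 1 | bin > nb] <- NA_integer_
  key <- interaction(cells$mouse_id, cells$section_ap_mm, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(cells)), key),
                               function(idx) {
    m <- cells[idx, , drop = FALSE]
    n <- vapply(seq_len(nb), function(b) sum(bin[idx] == b, na.rm = TRUE),
                numeric(1))
    data.frame(mouse_id = m$mouse_id[1], group = m$group[1],
               section_ap_mm = m$section_ap_mm[1],
               ml_bin = labs, n = n, percent = 100 * n / sum(n),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Distances from a ventral landmark
#'
#' For every cell in the given AP window, the distance from the
#' per-section ventral boundary (the "bottom" landmark): `y_mm -
#' landmark_y`. Cells below the landmark get signed negative distances and
#' are flagged with a message; the analysis proceeds with the signed
#' values.
#'
#' @param cells a `section_cell_table`.
#' @param ap_window_mm half-open AP window `[lo, hi)` selecting the
#'   sections to analyze; default `c(-3.6, -3.3)`, the middle part of the
#'   VTA.
#' @param landmark_y the ventral boundary: a single y (mm) applied to all
#'   sections, or a named vector keyed by `section_ap_mm`.
#' @return A `distance_sample`: list with `group`, `values_mm`, `kind =
#'   "landmark"`, `n`, `seed` (NA) and the empirical CDF `ecdf`.
#' @export
landmark_distance <- function(cells, ap_window_mm = c(-3.6, -3.3),
                              landmark_y = 0) {
  stopifnot(is.data.frame(cells))
  sel <- cells$section_ap_mm >= ap_window_mm[1] &
    cells$section_ap_mm < ap_window_mm[2]
  m <- cells[sel, , drop = FALSE]
  if (nrow(m) == 0) stop("no cells in the AP window", call. = FALSE)
  if (length(landmark_y) == 1L && is.null(names(landmark_y))) {
    lm <- rep(landmark_y, nrow(m))
  } else {
    key <- format(m$section_ap_mm)
    if (!all(key %in% names(landmark_y)))
      stop("landmark not defined for every section in the window",
           call. = FALSE)
    lm <- unname(landmark_y[key])
  }
  d <- m$y_mm - lm
  if (any(d < 0))
    message(sum(d < 0), " cell(s) below the landmark (negative distance)")
  distance_sample(d, group = paste(unique(m$group), collapse = "+"),
                  kind = "landmark")
}

distance_sample <- function(values, group, kind, seed = NA_integer_) {
  structure(list(group = group, values_mm = as.numeric(values),
                 kind = kind, n = length(values), seed = seed,
                 ecdf = stats::ecdf(values)),
            class = "distance_sample")
}

#' @export
print.distance_sample <- function(x, ...) {
  cat(sprintf("Distance sample (%s): group %s, n = %d, median %.3f mm\n",
              x$kind, x$group, x$n, stats::median(x$values_mm)))
  invisible(x)
}

#' Random paired-cell distances
#'
#' Samples `n_pairs` distinct unordered pairs of cells uniformly at random
#' from the pool of all within-section pairs (2D coordinates are only
#' comparable within a section), pooled across the mice present in
#' `cells`, and returns their Euclidean distances. If fewer distinct pairs
#' exist than requested, all pairs are returned and the achieved `n` is
#' reported. Cells are canonicalized (sorted by coordinates within
#' section) before pairing, so the result is invariant to row order.
#'
#' @param cells a `section_cell_table`.
#' @param n_pairs number of pairs to draw (default 1000).
#' @param seed RNG seed, recorded in the result.
#' @return A `distance_sample` with `kind = "paired"`.
#' @examples
#' cells <- gen_point_pattern(synth_config(n_cells = 80), seed = 2)
#' paired_distances(cells, n_pairs = 100, seed = 1)
#' @export
paired_distances <- function(cells, n_pairs = 1000, seed = 1L) {
  stopifnot(is.data.frame(cells))
  key <- interaction(cells$mouse_id, cells$section_ap_mm, drop = TRUE)
  secs <- split(seq_len(nrow(cells)), key)
  # canonical within-section order: sort by (x, y)
  secs <- lapply(secs, function(idx)
    idx[order(cells$x_mm[idx], cells$y_mm[idx])])
  ns <- vapply(secs, length, integer(1))
  secs <- secs[ns >= 2]
  ns <- ns[ns >= 2]
  if (length(secs) == 0)
    stop("need at least 2 cells in some section", call. = FALSE)
  npair_sec <- ns * (ns - 1) / 2
  total <- sum(npair_sec)

  pair_dist <- function(s, i, j) {
    a <- secs[[s]][i]; b <- secs[[s]][j]
    sqrt((cells$x_mm[a] - cells$x_mm[b])^2 +
         (cells$y_mm[a] - cells$y_mm[b])^2)
  }

  d <- with_seed(seed, {
    if (total <= 4 * n_pairs) {
      # enumerate every within-section pair, then subsample if needed
      all_pairs <- do.call(rbind, lapply(seq_along(secs), function(s) {
        cb <- utils::combn(length(secs[[s]]), 2)
        cbind(s, cb[1, ], cb[2, ])
      }))
      take <- if (total > n_pairs)
        all_pairs[sample.int(total, n_pairs), , drop = FALSE]
      else all_pairs
      vapply(seq_len(nrow(take)), function(k)
        pair_dist(take[k, 1], take[k, 2], take[k, 3]), numeric(1))
    } else {
      # rejection sampling of distinct pairs: section weighted by its pair
      # count, then an unordered pair inside it; duplicates are rejected
      seen <- new.env(hash = TRUE, size = 2L * n_pairs)
      out <- numeric(n_pairs)
      got <- 0L
      while (got < n_pairs) {
        s <- sample.int(length(secs), 1, prob = npair_sec)
        ij <- sort(sample.int(ns[s], 2))
        k <- paste(s, ij[1], ij[2])
        if (is.null(seen[[k]])) {
          assign(k, TRUE, envir = seen)
          got <- got + 1L
          out[got] <- pair_dist(s, ij[1], ij[2])
        }
      }
      out
    }
  })
  res <- distance_sample(d, group = paste(unique(cells$group), collapse = "+"),
                         kind = "paired", seed = seed)
  if (res$n < n_pairs)
    message("only ", res$n, " distinct pairs available (requested ",
            n_pairs, ")")
  res
}

#' Two-sample Kolmogorov-Smirnov comparison of distance distributions
#'
#' The two-sample KS statistic `D = sup |ECDF_a - ECDF_b|` with its
#' asymptotic p-value, the conventional test for comparing distance
#' distributions between groups.
#'
#' @param a,b `distance_sample` objects (or numeric vectors).
#' @return list with `D`, `p`, `n_a`, `n_b`.
#' @examples
#' x <- distance_sample(runif(50), "g1", "paired")
#' y <- distance_sample(runif(50, 0.5, 1.5), "g2", "paired")
#' ecdf_compare(x, y)$D
#' @export
ecdf_compare <- function(a, b) {
  va <- if (inherits(a, "distance_sample")) a$values_mm else as.numeric(a)
  vb <- if (inherits(b, "distance_sample")) b$values_mm else as.numeric(b)
  if (length(va) == 0 || length(vb) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(va, vb, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value),
       n_a = length(va), n_b = length(vb))
}

has_marker <- function(cells, marker) {
  vapply(strsplit(cells$markers, ";", fixed = TRUE),
         function(m) marker %in% m, logical(1))
}

#' Marker colocalization fraction
#'
#' The fraction of `base_marker`-positive cells that also carry
#' `co_marker`, overall or per AP bin (e.g. the TH+ fraction of
#' EGFP-tagged ensemble cells). A bin with zero base cells is reported as
#' missing, not zero.
#'
#' @param cells a `section_cell_table`.
#' @param base_marker,co_marker marker labels found in the `markers`
#'   column.
#' @param by `"overall"` for a single fraction, `"ap"` for a per-AP-bin
#'   table.
#' @param bin_mm AP bin width when `by = "ap"`.
#' @return A single fraction, or a data.frame with `ap_bin_mm`,
#'   `n_base`, `n_both`, `fraction`.
#' @export
colocalization_fraction <- function(cells, base_marker, co_marker,
                                    by = c("overall", "ap"), bin_mm = 0.1) {
  by <- match.arg(by)
  base <- has_marker(cells, base_marker)
  both <- base & has_marker(cells, co_marker)
  if (by == "overall") {
    if (sum(base) == 0) return(NA_real_)
    return(sum(both) / sum(base))
  }
  lo <- floor(min(cells$section_ap_mm) / bin_mm) * bin_mm
  bins <- round(lo + bin_mm *
                  floor(round((cells$section_ap_mm - lo) / bin_mm, 9)), 9)
  grid <- sort(unique(bins))
  nb <- vapply(grid, function(b) sum(base & bins == b), numeric(1))
  nc <- vapply(grid, function(b) sum(both & bins == b), numeric(1))
  data.frame(ap_bin_mm = grid, n_base = nb, n_both = nc,
             fraction = ifelse(nb > 0, nc / nb, NA_real_))
}
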