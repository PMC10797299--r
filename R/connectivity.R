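#' Normalized input index (per-region input fraction)
#'
#' For each mouse, a region's input-neuron count divided by the mouse's
#' total input-neuron count; fractions sum to 1 per mouse. A mouse with a
#' zero total is dropped (its fractions are undefined) with a message.
#'
#' @param counts a `region_count_table` (see [gen_tracing_counts()] or
#'   [read_count_table()]).
#' @param regions region column names; defaults to `attr(counts, "regions")`.
#' @return data.frame with `mouse_id`, `group`, then one fraction column
#'   per region; `attr(, "regions")` preserved.
#' @examples
#' cfg <- synth_config(region_names = c("A", "B"),
#'                     group_region_weights = list(g = c(A = 3, B = 1)),
#'                     n_mice_per_group = 1)
#' input_fraction(gen_tracing_counts(cfg, seed = 1))
#' @export
input_fraction <- function(counts, regions = attr(counts, "regions")) {
  stopifnot(is.data.frame(counts), !is.null(regions))
  mat <- as.matrix(counts[, regions, drop = FALSE])
  tot <- rowSums(mat)
  keep <- tot > 0
  if (any(!keep))
    message(sum(!keep), " mouse/mice with zero total input count dropped")
  out <- data.frame(mouse_id = counts$mouse_id[keep],
                    group = counts$group[keep],
                    stringsAsFactors = FALSE, check.names = FALSE)
  out[regions] <- as.data.frame(mat[keep, , drop = FALSE] / tot[keep],
                                check.names = FALSE)
  structure(out, regions = regions)
}

signal_value_table <- function(signals, value, regions) {
  out <- data.frame(mouse_id = signals$mouse_id, group = signals$group,
                    region = signals$region, value = value,
                    stringsAsFactors = FALSE)
  structure(out, regions = regions)
}

#' Axonal arborization per neuron
#'
#' A region's supra-threshold axonal arborization area normalized by the
#' number of EGFP+ cells in the source region (VTA) of the same mouse;
#' units mm^2 per cell.
#'
#' @param signals a `region_signal_table` (long format; see
#'   [gen_region_signals()] or [read_signal_table()]).
#' @return data.frame `mouse_id`, `group`, `region`, `value`.
#' @export
arborization_per_neuron <- function(signals) {
  stopifnot(is.data.frame(signals))
  if (any(signals$vta_egfp_count <= 0))
    stop("vta_egfp_count must be positive for every mouse", call. = FALSE)
  signal_value_table(signals,
                     signals$arborization_area_mm2 / signals$vta_egfp_count,
                     attr(signals, "regions"))
}

#' Axon density
#'
#' The ratio between a region's integrated axonal fluorescence density and
#' the VTA (source region) integrated density of the same mouse;
#' dimensionless.
#'
#' @inheritParams arborization_per_neuron
#' @return data.frame `mouse_id`, `group`, `region`, `value`.
#' @export
axon_density <- function(signals) {
  stopifnot(is.data.frame(signals))
  if (any(signals$vta_integrated_density <= 0))
    stop("vta_integrated_density must be positive for every mouse",
         call. = FALSE)
  signal_value_table(signals,
                     signals$integrated_density / signals$vta_integrated_density,
                     attr(signals, "regions"))
}

#' Density fraction
#'
#' A region's integrated axonal density divided by the summed density over
#' all target regions of the same mouse. The VTA is the source, not a
#' target, so its own density never enters the denominator; fractions sum
#' to 1 per mouse. Mice with zero total are dropped with a message.
#'
#' @inheritParams arborization_per_neuron
#' @return data.frame `mouse_id`, `group`, `region`, `value`.
#' @export
density_fraction <- function(signals) {
  stopifnot(is.data.frame(signals))
  tot <- stats::ave(signals$integrated_density, signals$mouse_id, FUN = sum)
  keep <- tot > 0
  if (any(!keep))
    message(length(unique(signals$mouse_id[!keep])),
            " mouse/mice with zero total target density dropped")
  out <- signal_value_table(signals[keep, , drop = FALSE],
                            signals$integrated_density[keep] / tot[keep],
                            attr(signals, "regions"))
  out
}

#' Pivot a per-mouse per-region value table to a feature matrix
#'
#' Builds the mice-by-regions matrix (plus the per-mouse class labels)
#' that the random-forest ranking consumes.
#'
#' @param values data.frame `mouse_id`, `group`, `region`, `value` (from
#'   [arborization_per_neuron()], [axon_density()] or
#'   [density_fraction()]), or a wide fraction table from
#'   [input_fraction()].
#' @return A `feature_table`: list with `x` (matrix, rownames = mice,
#'   colnames = regions) and `labels` (factor of groups, one per mouse).
#' @export
as_feature_table <- function(values) {
  stopifnot(is.data.frame(values))
  if ("region" %in% names(values)) {
    mice <- sort(unique(values$mouse_id))
    regions <- attr(values, "regions") %||% sort(unique(values$region))
    x <- matrix(NA_real_, length(mice), length(regions),
                dimnames = list(mice, regions))
    x[cbind(match(values$mouse_id, mice),
            match(values$region, regions))] <- values$value
    labels <- values$group[match(mice, values$mouse_id)]
  } else {
    regions <- attr(values, "regions")
    ord <- order(values$mouse_id)
    x <- as.matrix(values[ord, regions, drop = FALSE])
    rownames(x) <- values$mouse_id[ord]
    labels <- values$group[ord]
  }
  if (anyNA(x)) stop("feature table has missing values", call. = FALSE)
  structure(list(x = x, labels = factor(labels)), class = "feature_table")
}

#' Group summary (mean and SEM) of a per-mouse per-region value table
#'
#' @param values data.frame `mouse_id`, `group`, `region`, `value`.
#' @return data.frame `group`, `region`, `n`, `mean`, `sem`.
#' @export
group_summary <- function(values) {
  stopifnot(all(c("group", "region", "value") %in% names(values)))
  keys <- unique(values[c("group", "region")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    v <- values$value[values$group == keys$group[i] &
                        values$region == keys$region[i]]
    data.frame(group = keys$group[i], region = keys$region[i],
               n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$region, out$group), ]
}
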