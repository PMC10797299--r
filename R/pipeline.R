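#' Run the analysis pipeline
#'
#' Drives every stage of the pipeline over one output directory.
#' `"simulate"` generates all synthetic inputs (cell tables, tracing
#' counts, region signals, a section image, a photometry trace) with
#' ground truth; the analysis stages read those files back and write their
#' result tables; `"all"` chains everything. In the simulated study the
#' first group's cells follow the clustered (Thomas) pattern and the
#' remaining groups the dispersed (Poisson) pattern, mirroring the
#' clustered-versus-dispersed contrast the spatial statistics are built to
#' detect. Every run ends with a `manifest.json` recording the
#' configuration, the seed and the MD5 digest of every output file.
#'
#' @param config a [synth_config()] or the path of a YAML configuration.
#' @param stage one of `"simulate"`, `"spatial"`, `"quantify-images"`,
#'   `"connectivity"`, `"rank"`, `"photometry"`, `"all"`.
#' @param out_dir output directory (created if needed).
#' @param seed global seed; every stage derives its substreams from it.
#' @param strict fail on malformed input rows instead of dropping them.
#' @return `out_dir`, invisibly.
#' @examples
#' \donttest{
#' cfg <- synth_config(n_cells = 100, n_mice_per_group = 2,
#'                     image_size = 64, blobs_per_image = 3)
#' out <- run_pipeline(cfg, "all", tempfile("run"), seed = 1)
#' list.files(out)
#' }
#' @export
run_pipeline <- function(config, stage = c("all", "simulate", "spatial",
                                           "quantify-images", "connectivity",
                                           "rank", "photometry"),
                         out_dir, seed = NULL, strict = TRUE) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "synth_config"))
  seed <- as.integer(seed %||% config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (stage %in% c("all", "simulate")) stage_simulate(config, out_dir, seed)
  if (stage %in% c("all", "spatial")) stage_spatial(config, out_dir, seed, strict)
  if (stage %in% c("all", "quantify-images")) stage_images(config, out_dir)
  if (stage %in% c("all", "connectivity")) stage_connectivity(out_dir, strict)
  if (stage %in% c("all", "rank")) stage_rank(out_dir, seed, strict)
  if (stage %in% c("all", "photometry")) stage_photometry(out_dir)

  write_manifest(out_dir, command = paste("ensembleatlas", stage), config, seed)
  invisible(out_dir)
}

stage_simulate <- function(config, out_dir, seed) {
  groups <- names(config$group_region_weights)
  patterns <- stats::setNames(
    c("thomas", rep("poisson", length(groups) - 1L)), groups)
  cells <- gen_cell_tables(config, seed = seed, patterns = patterns)
  write_cell_table(cells, file.path(out_dir, "cells.tsv"))

  counts <- gen_tracing_counts(config, seed = seed)
  write_count_table(counts, file.path(out_dir, "counts.tsv"))

  signals <- gen_region_signals(config, seed = seed)
  write_signal_table(signals, file.path(out_dir, "signals.tsv"))

  img <- gen_section_image(config, seed = derive_seed(seed, 3000L))
  write_image(img, file.path(out_dir, "section_image.tif"))

  trace <- gen_photometry(config, seed = derive_seed(seed, 4000L))
  write_photometry(trace, file.path(out_dir, "photometry.tsv"),
                   file.path(out_dir, "photometry_events.tsv"))

  truth <- list(
    cell_patterns = as.list(patterns),
    count_probs = lapply(attr(counts, "truth"), as.list),
    image = list(n_blobs = attr(img, "truth")$n_blobs,
                 axon_area_px = attr(img, "truth")$axon_area_px),
    photometry = attr(trace, "truth")[c("amplitude", "tau_s")])
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

stage_spatial <- function(config, out_dir, seed, strict) {
  cells <- read_cell_table(file.path(out_dir, "cells.tsv"), strict = strict)
  write_tsv(ap_profile(cells), file.path(out_dir, "ap_profile.tsv"))
  write_tsv(ml_profile(cells), file.path(out_dir, "ml_profile.tsv"))

  groups <- unique(cells$group)
  lmk <- do.call(rbind, lapply(groups, function(g) {
    ds <- landmark_distance(cells[cells$group == g, , drop = FALSE],
                            landmark_y = config$region_extent$dv[1])
    data.frame(group = g, distance_mm = ds$values_mm,
               stringsAsFactors = FALSE)
  }))
  write_tsv(lmk, file.path(out_dir, "landmark_distances.tsv"))

  pds <- lapply(groups, function(g)
    paired_distances(cells[cells$group == g, , drop = FALSE],
                     n_pairs = 1000,
                     seed = derive_seed(seed, 5000L + match(g, groups))))
  names(pds) <- groups
  write_tsv(do.call(rbind, lapply(groups, function(g)
    data.frame(group = g, distance_mm = pds[[g]]$values_mm,
               stringsAsFactors = FALSE))),
    file.path(out_dir, "paired_distances.tsv"))

  pairs <- utils::combn(groups, 2)
  ks <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    cmp <- ecdf_compare(pds[[pairs[1, i]]], pds[[pairs[2, i]]])
    data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
               D = cmp$D, p = cmp$p, stringsAsFactors = FALSE)
  }))
  write_tsv(ks, file.path(out_dir, "ks_tests.tsv"))

  coloc <- do.call(rbind, lapply(groups, function(g) {
    cf <- colocalization_fraction(cells[cells$group == g, , drop = FALSE],
                                  "EGFP", "TH", by = "ap")
    cbind(group = g, cf, stringsAsFactors = FALSE)
  }))
  write_tsv(coloc, file.path(out_dir, "colocalization.tsv"))
  invisible(NULL)
}

stage_images <- function(config, out_dir) {
  img <- read_image(file.path(out_dir, "section_image.tif"))
  bg <- estimate_background(img, "background")
  rois <- setdiff(names(img$rois), c("background", "full"))
  metrics <- do.call(rbind, lapply(rois, function(r)
    region_axon_metrics(img, r, background = bg, k = 3)))
  write_tsv(metrics, file.path(out_dir, "image_metrics.tsv"))

  cc <- count_cells(threshold_mask(img, bg, k = 3) & img$rois$cells,
                    min_area_px = 4, pixel_size_mm = img$pixel_size_mm)
  write_tsv(cbind(data.frame(cell = seq_len(nrow(cc$centroids))),
                  cc$centroids),
            file.path(out_dir, "cell_counts.tsv"))

  if (length(img$cell_masks %||% list()) > 0) {
    pci <- percell_intensity(img, background = bg, k = 1.5)
    write_tsv(data.frame(cell = seq_along(pci), integrated_density = pci),
              file.path(out_dir, "percell_intensity.tsv"))
  }
  invisible(NULL)
}

stage_connectivity <- function(out_dir, strict) {
  counts <- read_count_table(file.path(out_dir, "counts.tsv"), strict = strict)
  signals <- read_signal_table(file.path(out_dir, "signals.tsv"),
                               strict = strict)
  write_tsv(input_fraction(counts), file.path(out_dir, "input_fraction.tsv"))
  idx <- list(arborization_per_neuron = arborization_per_neuron(signals),
              axon_density = axon_density(signals),
              density_fraction = density_fraction(signals))
  for (nm in names(idx)) {
    write_tsv(idx[[nm]], file.path(out_dir, paste0("index_", nm, ".tsv")))
    write_tsv(group_summary(idx[[nm]]),
              file.path(out_dir, paste0("summary_", nm, ".tsv")))
  }
  invisible(NULL)
}

stage_rank <- function(out_dir, seed, strict) {
  signals <- read_signal_table(file.path(out_dir, "signals.tsv"),
                               strict = strict)
  idx <- list(arborization_per_neuron = arborization_per_neuron(signals),
              axon_density = axon_density(signals),
              density_fraction = density_fraction(signals))
  gt <- lapply(seq_along(idx), function(i)
    gini_importance(as_feature_table(idx[[i]]), n_trees = 500,
                    seed = derive_seed(seed, 6000L + i)))
  names(gt) <- names(idx)
  gini_df <- data.frame(region = names(gt[[1]]),
                        vapply(gt, function(g) unname(g[names(gt[[1]])]),
                               numeric(length(gt[[1]]))),
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(gini_df, file.path(out_dir, "gini_importance.tsv"))
  comp <- composite_ranking(gt, top_k = 10)
  write_tsv(as.data.frame(comp), file.path(out_dir, "composite_ranking.tsv"))
  jsonlite::write_json(
    list(n_trees = 500, top_k = 10,
         seeds = vapply(seq_along(idx), function(i)
           derive_seed(seed, 6000L + i), integer(1)),
         indexes = names(idx)),
    file.path(out_dir, "ranking_parameters.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

stage_photometry <- function(out_dir) {
  trace <- read_photometry(file.path(out_dir, "photometry.tsv"),
                           file.path(out_dir, "photometry_events.tsv"))
  rows <- list()
  for (ch in c("f470", if (!is.null(trace$f410)) "f410")) {
    ep <- dff(trace, baseline_s = 2, window_s = c(-2, 6), first_k = 4,
              channel = ch)
    a <- epoch_auc(ep, window_s = c(0, 5))
    p <- epoch_peak(ep, window_s = c(0, 5))
    rows[[ch]] <- data.frame(channel = ch,
                             event = seq_along(a$per_event),
                             auc_0_5s = a$per_event,
                             peak_0_5s = p$per_event,
                             stringsAsFactors = FALSE)
  }
  write_tsv(do.call(rbind, rows), file.path(out_dir, "photometry_summary.tsv"))
  invisible(NULL)
}
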