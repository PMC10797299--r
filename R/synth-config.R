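#' Brain regions used as default vocabularies
#'
#' Abbreviated region names for the major afferent sources and efferent
#' targets of the ventral tegmental area (VTA), as conventionally used in
#' mouse tracing studies (e.g. AcbC = accumbens core, DMStr = dorsal medial
#' striatum, MEZ = hypothalamic medial zone, VP = ventral pallidum,
#' ZI = zona incerta, LHb = lateral habenula).
#'
#' `vta_input_regions` (20 regions) is the default vocabulary for
#' input-count tables; `vta_output_regions` (24 regions) for axonal-output
#' tables. Both are plain character vectors and fully replaceable through
#' [synth_config()].
#'
#' @format Character vectors of region abbreviations.
#' @name region_vocabularies
NULL

#' @rdname region_vocabularies
#' @export
vta_input_regions <- c(
  "AcbC", "AcbSh medial", "AcbSh lateral", "BNST", "DLStr", "DMStr",
  "DORpm", "DORsm", "DR", "Gpe", "LDT", "LH", "LHb", "MEZ", "mPFC",
  "PO", "PVH", "sAMY", "VP", "ZI"
)

#' @rdname region_vocabularies
#' @export
vta_output_regions <- c(
  "AcbC", "AcbSh medial", "AcbSh lateral", "BLA", "BMA", "BNST", "DLStr",
  "DMStr", "DORpm", "DORsm", "DR", "Gpe", "LA", "LDT", "LH", "LHb", "MEZ",
  "MHb", "mPFC", "PO", "PVH", "sAMY", "VP", "ZI"
)

default_group_weights <- function(regions) {
  base <- stats::setNames(rep(1, length(regions)), regions)
  mor <- base
  shock <- base
  # group-specific biases: the morphine-tagged ensemble receives relatively
  # more input from DMStr and MEZ, the shock-tagged ensemble from VP and LHb
  for (r in intersect(c("DMStr", "MEZ"), regions)) mor[r] <- 2
  for (r in intersect(c("VP", "LHb"), regions)) shock[r] <- 2
  list("Mor-Ens" = mor, "Shock-Ens" = shock)
}

#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the synthetic ground-truth generators: the 3D
#' extent of the region of interest, the spatial point process of labeled
#' cells, the multinomial region-count model for monosynaptic tracing, the
#' section-image model (Gaussian cell blobs and axon texture over noisy
#' background), and the two-channel photometry trace model.
#'
#' @param region_extent list with numeric length-2 elements `ap`, `ml`, `dv`:
#'   the bounding box of the region in mm. AP is signed mm from bregma
#'   (negative = posterior); ML is distance from the midline; DV is a local
#'   dorsoventral coordinate with larger values more dorsal, so `dv[1]` is
#'   the ventral boundary.
#' @param n_cells number of labeled cells per mouse.
#' @param pattern spatial point process, `"poisson"` (uniform, the dispersed
#'   null) or `"thomas"` (Poisson cluster parents with isotropic Gaussian
#'   offspring, the clustered alternative).
#' @param cluster_rate Thomas parent intensity, clusters per mm^3.
#' @param cluster_sd Thomas offspring dispersion, mm.
#' @param ventral_gradient exponential decay rate (1/mm) of cell density
#'   with distance from the ventral boundary; 0 means uniform in DV.
#' @param n_mice_per_group mice simulated per group.
#' @param region_names region vocabulary for count/signal tables.
#' @param group_region_weights named list (one element per group) of
#'   nonnegative per-region weight vectors; weights are normalized to
#'   multinomial probabilities.
#' @param counts_per_mouse total input-neuron count drawn per mouse.
#' @param starter_mean Poisson mean of the starter-neuron count per mouse.
#' @param marker_probs named vector of per-cell marker probabilities
#'   (every cell additionally carries the `cFos` marker).
#' @param image_size section image side length, pixels.
#' @param pixel_size_mm physical pixel size, mm/pixel.
#' @param cell_radius_px nominal cell blob radius, pixels.
#' @param blobs_per_image cell blobs planted per section image.
#' @param axon_area_px exact pixel area of the planted axon texture
#'   (0 = none).
#' @param background_mean,background_sd image background grayscale
#'   mean and standard deviation.
#' @param signal_amplitude peak grayscale amplitude of planted signal
#'   above background.
#' @param sampling_rate_hz photometry sampling rate, Hz.
#' @param transient_amplitude event-locked transient amplitude, dF/F units.
#' @param transient_tau_s transient exponential decay constant, s.
#' @param photometry_noise_sd channel noise standard deviation as a
#'   fraction of the channel baseline.
#' @param baseline_f470,baseline_f410 baseline fluorescence of the
#'   calcium-dependent (470 nm) and isosbestic (410 nm) channels,
#'   arbitrary units.
#' @param event_times_s default event onset times, s.
#' @param seed default RNG seed for the generators.
#'
#' @return An object of class `synth_config` (a validated named list).
#' @seealso [gen_point_pattern()], [gen_tracing_counts()],
#'   [gen_section_image()], [gen_photometry()]
#' @examples
#' cfg <- synth_config(n_cells = 200, pattern = "thomas", cluster_sd = 0.03)
#' cells <- gen_point_pattern(cfg, seed = 1)
#' nrow(cells)
#' @export
synth_config <- function(region_extent = list(ap = c(-3.8, -3.0),
                                              ml = c(0, 0.9),
                                              dv = c(0, 1.0)),
                         n_cells = 500L,
                         pattern = c("poisson", "thomas"),
                         cluster_rate = 60,
                         cluster_sd = 0.05,
                         ventral_gradient = 0,
                         n_mice_per_group = 6L,
                         region_names = vta_input_regions,
                         group_region_weights = NULL,
                         counts_per_mouse = 4000L,
                         starter_mean = 150,
                         marker_probs = c(EGFP = 1, TH = 0.5, GABA = 0.45),
                         image_size = 256L,
                         pixel_size_mm = 0.002,
                         cell_radius_px = 4,
                         blobs_per_image = 12L,
                         axon_area_px = 0L,
                         background_mean = 20,
                         background_sd = 2,
                         signal_amplitude = 100,
                         sampling_rate_hz = 100,
                         transient_amplitude = 0.1,
                         transient_tau_s = 2,
                         photometry_noise_sd = 0.005,
                         baseline_f470 = 100,
                         baseline_f410 = 80,
                         event_times_s = c(30, 55, 80, 105),
                         seed = 1L) {
  pattern <- match.arg(pattern)
  cfg <- list(
    region_extent = region_extent, n_cells = as.integer(n_cells),
    pattern = pattern, cluster_rate = cluster_rate, cluster_sd = cluster_sd,
    ventral_gradient = ventral_gradient,
    n_mice_per_group = as.integer(n_mice_per_group),
    region_names = region_names,
    group_region_weights = group_region_weights %||%
      default_group_weights(region_names),
    counts_per_mouse = as.integer(counts_per_mouse),
    starter_mean = starter_mean, marker_probs = marker_probs,
    image_size = as.integer(image_size), pixel_size_mm = pixel_size_mm,
    cell_radius_px = cell_radius_px,
    blobs_per_image = as.integer(blobs_per_image),
    axon_area_px = as.integer(axon_area_px),
    background_mean = background_mean, background_sd = background_sd,
    signal_amplitude = signal_amplitude,
    sampling_rate_hz = sampling_rate_hz,
    transient_amplitude = transient_amplitude,
    transient_tau_s = transient_tau_s,
    photometry_noise_sd = photometry_noise_sd,
    baseline_f470 = baseline_f470, baseline_f410 = baseline_f410,
    event_times_s = event_times_s,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  ext <- cfg$region_extent
  if (!is.list(ext) || !all(c("ap", "ml", "dv") %in% names(ext)))
    stop_field("region_extent", "must be a list with elements ap, ml, dv")
  for (ax in c("ap", "ml", "dv")) {
    v <- ext[[ax]]
    if (!is.numeric(v) || length(v) != 2 || any(!is.finite(v)))
      stop_field("region_extent", sprintf("element '%s' must be two finite numbers", ax))
    if (v[2] < v[1])
      stop_field("region_extent", sprintf("element '%s' must be increasing", ax))
  }
  nonneg <- c("cluster_rate", "cluster_sd", "ventral_gradient",
              "counts_per_mouse", "starter_mean", "cell_radius_px",
              "background_mean", "background_sd", "signal_amplitude",
              "transient_amplitude", "transient_tau_s",
              "photometry_noise_sd", "axon_area_px")
  for (f in nonneg) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stop_field(f, "must be a single nonnegative finite number")
  }
  if (cfg$n_cells < 0) stop_field("n_cells", "must be nonnegative")
  if (cfg$n_mice_per_group < 1) stop_field("n_mice_per_group", "must be >= 1")
  if (cfg$image_size < 1) stop_field("image_size", "must be positive")
  if (cfg$pixel_size_mm <= 0) stop_field("pixel_size_mm", "must be positive")
  if (cfg$sampling_rate_hz <= 0) stop_field("sampling_rate_hz", "must be positive")
  if (cfg$baseline_f470 <= 0) stop_field("baseline_f470", "must be positive")
  if (cfg$baseline_f410 <= 0) stop_field("baseline_f410", "must be positive")
  if (cfg$pattern == "thomas" && (cfg$cluster_rate <= 0 || cfg$cluster_sd <= 0))
    stop_field("pattern", "pattern 'thomas' requires cluster_rate > 0 and cluster_sd > 0")
  if (length(cfg$region_names) < 1 || anyDuplicated(cfg$region_names))
    stop_field("region_names", "must be a non-empty set of unique names")
  gw <- cfg$group_region_weights
  if (!is.list(gw) || is.null(names(gw)) || length(gw) < 1)
    stop_field("group_region_weights", "must be a named list of weight vectors")
  for (g in names(gw)) {
    w <- gw[[g]]
    if (!all(cfg$region_names %in% names(w)))
      stop_field("group_region_weights",
                 sprintf("group '%s' lacks weights for some regions", g))
    if (any(w < 0) || !any(w[cfg$region_names] > 0))
      stop_field("group_region_weights",
                 sprintf("group '%s' needs nonnegative weights with at least one positive entry", g))
  }
  if (any(cfg$marker_probs < 0 | cfg$marker_probs > 1))
    stop_field("marker_probs", "must be probabilities in [0, 1]")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  ext <- x$region_extent
  cat("Synthetic-data configuration\n")
  cat(sprintf("  extent (mm): AP [%g, %g]  ML [%g, %g]  DV [%g, %g]\n",
              ext$ap[1], ext$ap[2], ext$ml[1], ext$ml[2], ext$dv[1], ext$dv[2]))
  cat(sprintf("  point pattern: %s, %d cells/mouse, ventral gradient %g /mm\n",
              x$pattern, x$n_cells, x$ventral_gradient))
  cat(sprintf("  groups: %s (%d mice each)\n",
              paste(names(x$group_region_weights), collapse = ", "),
              x$n_mice_per_group))
  cat(sprintf("  regions: %d; counts/mouse: %d; starter mean: %g\n",
              length(x$region_names), x$counts_per_mouse, x$starter_mean))
  cat(sprintf("  image: %dpx @ %g mm/px; photometry: %g Hz, A=%g, tau=%g s\n",
              x$image_size, x$pixel_size_mm, x$sampling_rate_hz,
              x$transient_amplitude, x$transient_tau_s))
  invisible(x)
}
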