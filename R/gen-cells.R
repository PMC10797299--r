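#' Simulate a labeled-cell point pattern for one mouse
#'
#' Draws `n_cells` cell positions inside the configured 3D region, either
#' uniformly (`pattern = "poisson"`, the dispersed null) or from a
#' Thomas-type cluster process (`pattern = "thomas"`: Poisson parents,
#' isotropic Gaussian offspring with total count fixed at `n_cells`).
#' A positive `ventral_gradient` g makes the dorsoventral density decay as
#' exp(-g * d) with distance d from the ventral boundary, emulating ventral
#' enrichment of an ensemble. Cells are assigned to coronal sections by
#' binning the AP coordinate into 0.1 mm slabs.
#'
#' @param config a [synth_config()].
#' @param seed RNG seed.
#' @param mouse_id,group identifiers stamped on every record.
#' @return A `section_cell_table`: a data.frame with one row per cell and
#'   columns `mouse_id`, `group`, `section_ap_mm` (lower edge of the 0.1 mm
#'   slab), `x_mm` (signed ML), `y_mm` (DV, larger = more dorsal),
#'   `markers` (semicolon-separated labels), `section_area_mm2`.
#'   The generating ground truth (pattern and its parameters) is attached
#'   as `attr(, "truth")`.
#' @examples
#' cfg <- synth_config(n_cells = 100)
#' head(gen_point_pattern(cfg, seed = 1))
#' @export
gen_point_pattern <- function(config, seed = config$seed,
                              mouse_id = "mouse01", group = "Mor-Ens") {
  stopifnot(inherits(config, "synth_config"))
  ext <- config$region_extent
  vol <- prod(vapply(ext, diff, numeric(1)))
  if (vol <= 0)
    stop("impossible geometry: region_extent has zero volume", call. = FALSE)
  n <- config$n_cells
  g <- config$ventral_gradient

  pts <- with_seed(seed, {
    if (config$pattern == "poisson") {
      data.frame(ap = stats::runif(n, ext$ap[1], ext$ap[2]),
                 ml = stats::runif(n, ext$ml[1], ext$ml[2]),
                 dv = sample_dv(n, ext$dv, g),
                 side = sample(c(-1, 1), n, replace = TRUE))
    } else {
      n_par <- max(1L, stats::rpois(1, config$cluster_rate * vol))
      par <- data.frame(ap = stats::runif(n_par, ext$ap[1], ext$ap[2]),
                        ml = stats::runif(n_par, ext$ml[1], ext$ml[2]),
                        dv = sample_dv(n_par, ext$dv, g),
                        # the hemisphere belongs to the cluster: offspring
                        # of one parent stay on one side of the midline
                        side = sample(c(-1, 1), n_par, replace = TRUE))
      assign_par <- sample.int(n_par, n, replace = TRUE)
      out <- matrix(NA_real_, n, 3)
      todo <- seq_len(n)
      # redraw Gaussian offsets until every offspring falls inside the box
      while (length(todo)) {
        cand <- cbind(par$ap[assign_par[todo]],
                      par$ml[assign_par[todo]],
                      par$dv[assign_par[todo]]) +
          matrix(stats::rnorm(3 * length(todo), 0, config$cluster_sd),
                 ncol = 3)
        ok <- cand[, 1] >= ext$ap[1] & cand[, 1] <= ext$ap[2] &
          cand[, 2] >= ext$ml[1] & cand[, 2] <= ext$ml[2] &
          cand[, 3] >= ext$dv[1] & cand[, 3] <= ext$dv[2]
        out[todo[ok], ] <- cand[ok, , drop = FALSE]
        todo <- todo[!ok]
      }
      data.frame(ap = out[, 1], ml = out[, 2], dv = out[, 3],
                 side = par$side[assign_par])
    }
  })

  markers <- with_seed(derive_seed(seed, 1L), {
    flags <- vapply(names(config$marker_probs), function(m) {
      stats::runif(n) < config$marker_probs[[m]]
    }, logical(n))
    if (n == 1L) flags <- matrix(flags, nrow = 1)
    apply(flags, 1, function(f)
      paste(c("cFos", names(config$marker_probs)[f]), collapse = ";"))
  })
  if (n == 0L) markers <- character(0)

  slab <- floor(round((pts$ap - ext$ap[1]) / 0.1, 9))
  section_ap <- round(ext$ap[1] + 0.1 * slab, 9)

  out <- data.frame(
    mouse_id = rep(mouse_id, n), group = rep(group, n),
    section_ap_mm = section_ap,
    x_mm = pts$side * pts$ml, y_mm = pts$dv,
    markers = markers,
    section_area_mm2 = rep(diff(ext$ml) * diff(ext$dv), n),
    stringsAsFactors = FALSE
  )
  structure(out,
            class = c("section_cell_table", "data.frame"),
            truth = list(pattern = config$pattern,
                         cluster_rate = config$cluster_rate,
                         cluster_sd = config$cluster_sd,
                         ventral_gradient = g,
                         extent = ext, seed = seed))
}

# Inverse-CDF sampling of the DV coordinate: density proportional to
# exp(-g * (y - dv_min)), i.e. exponential enrichment toward the ventral
# boundary; g = 0 reduces to uniform.
sample_dv <- function(n, dv, g) {
  if (g <= 0) return(stats::runif(n, dv[1], dv[2]))
  h <- diff(dv)
  u <- stats::runif(n)
  dv[1] - log(1 - u * (1 - exp(-g * h))) / g
}

#' Simulate labeled-cell tables for every mouse of every group
#'
#' Fans the global seed out to per-mouse substreams with fixed offsets, so
#' that adding a mouse or a group never changes the cells of earlier mice.
#'
#' @param config a [synth_config()].
#' @param seed global RNG seed.
#' @param patterns optional named character vector giving each group its
#'   point pattern (defaults to `config$pattern` for all groups).
#' @return A `section_cell_table` covering all groups and mice.
#' @export
gen_cell_tables <- function(config, seed = config$seed, patterns = NULL) {
  stopifnot(inherits(config, "synth_config"))
  groups <- names(config$group_region_weights)
  tabs <- list()
  for (gi in seq_along(groups)) {
    grp <- groups[gi]
    cfg_g <- config
    if (!is.null(patterns) && grp %in% names(patterns)) {
      cfg_g$pattern <- match.arg(patterns[[grp]], c("poisson", "thomas"))
      validate_synth_config(cfg_g)
      class(cfg_g) <- "synth_config"
    }
    for (mi in seq_len(config$n_mice_per_group)) {
      ms <- derive_seed(seed, 100L * gi + mi)
      tabs[[length(tabs) + 1L]] <- gen_point_pattern(
        cfg_g, seed = ms,
        mouse_id = sprintf("%s_m%02d", gsub("[^A-Za-z0-9]+", "", grp), mi),
        group = grp)
    }
  }
  out <- do.call(rbind, lapply(tabs, as.data.frame))
  structure(out, class = c("section_cell_table", "data.frame"),
            truth = lapply(tabs, attr, "truth"))
}
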