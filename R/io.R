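# Readers and writers for the pipeline's interchange formats: TSV tables
# with declared headers, single-channel TIFF images with a JSON sidecar,
# and the YAML configuration.

cell_table_cols <- c("mouse_id", "group", "section_ap_mm", "x_mm", "y_mm",
                     "markers", "section_area_mm2")
signal_table_cols <- c("mouse_id", "group", "region",
                       "arborization_area_mm2", "integrated_density",
                       "roi_area_mm2", "vta_egfp_count",
                       "vta_integrated_density")

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s) %s; found: %s", path,
                 paste(missing, collapse = ", "),
                 paste(names(df), collapse = ", ")), call. = FALSE)
}

drop_bad_rows <- function(df, bad, path, strict) {
  if (!any(bad)) return(df)
  lines <- which(bad) + 1L   # header is line 1
  if (strict)
    stop(sprintf("%s: malformed row(s) at line(s) %s", path,
                 paste(lines, collapse = ", ")), call. = FALSE)
  message(sprintf("%s: dropped %d malformed row(s) (line(s) %s)", path,
                  sum(bad), paste(lines, collapse = ", ")))
  df[!bad, , drop = FALSE]
}

#' Read and write labeled-cell tables
#'
#' TSV with columns `mouse_id`, `group`, `section_ap_mm`, `x_mm`, `y_mm`,
#' `markers`, `section_area_mm2`. In strict mode a malformed row
#' (non-numeric coordinates or nonpositive section area) fails with its
#' line number; in lenient mode it is dropped with a message.
#'
#' @param path file path.
#' @param strict fail on malformed rows (default) instead of dropping.
#' @param cells a `section_cell_table`.
#' @return `read_cell_table()` a `section_cell_table`;
#'   `write_cell_table()` the path, invisibly.
#' @export
read_cell_table <- function(path, strict = TRUE) {
  df <- read_tsv(path)
  check_columns(df, cell_table_cols, path)
  for (cc in c("section_ap_mm", "x_mm", "y_mm", "section_area_mm2"))
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  bad <- !is.finite(df$section_ap_mm) | !is.finite(df$x_mm) |
    !is.finite(df$y_mm) | !is.finite(df$section_area_mm2) |
    df$section_area_mm2 <= 0
  df <- drop_bad_rows(df, bad, path, strict)
  structure(df, class = c("section_cell_table", "data.frame"))
}

#' @rdname read_cell_table
#' @export
write_cell_table <- function(cells, path) write_tsv(as.data.frame(cells), path)

#' Read and write tracing count tables
#'
#' TSV with columns `mouse_id`, `group`, `starter_count`, then one integer
#' column per region; every non-key column is taken as a region.
#'
#' @param path file path.
#' @param strict fail on malformed rows (default) instead of dropping.
#' @param counts a `region_count_table`.
#' @return `read_count_table()` a `region_count_table` with
#'   `attr(, "regions")`.
#' @export
read_count_table <- function(path, strict = TRUE) {
  df <- read_tsv(path)
  check_columns(df, c("mouse_id", "group", "starter_count"), path)
  regions <- setdiff(names(df), c("mouse_id", "group", "starter_count"))
  if (length(regions) == 0)
    stop(sprintf("%s: no region columns found", path), call. = FALSE)
  for (cc in c("starter_count", regions))
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  bad <- Reduce(`|`, lapply(df[c("starter_count", regions)],
                            function(v) !is.finite(v) | v < 0))
  df <- drop_bad_rows(df, bad, path, strict)
  structure(df, class = c("region_count_table", "data.frame"),
            regions = regions)
}

#' @rdname read_count_table
#' @export
write_count_table <- function(counts, path) write_tsv(as.data.frame(counts), path)

#' Read and write region signal tables
#'
#' Long TSV with columns `mouse_id`, `group`, `region`,
#' `arborization_area_mm2`, `integrated_density`, `roi_area_mm2`,
#' `vta_egfp_count`, `vta_integrated_density`.
#'
#' @param path file path.
#' @param strict fail on malformed rows (default) instead of dropping.
#' @param signals a `region_signal_table`.
#' @return `read_signal_table()` a `region_signal_table` with
#'   `attr(, "regions")`.
#' @export
read_signal_table <- function(path, strict = TRUE) {
  df <- read_tsv(path)
  check_columns(df, signal_table_cols, path)
  num <- setdiff(signal_table_cols, c("mouse_id", "group", "region"))
  for (cc in num) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  bad <- Reduce(`|`, lapply(df[num], function(v) !is.finite(v))) |
    df$arborization_area_mm2 < 0 | df$integrated_density < 0 |
    df$roi_area_mm2 <= 0
  df <- drop_bad_rows(df, bad, path, strict)
  structure(df, class = c("region_signal_table", "data.frame"),
            regions = unique(df$region))
}

#' @rdname read_signal_table
#' @export
write_signal_table <- function(signals, path) write_tsv(as.data.frame(signals), path)

#' Read and write labeled images as TIFF
#'
#' The image is stored as a single-channel 16-bit TIFF (gray values are
#' rounded integers well inside the 16-bit range) next to a JSON sidecar
#' `<path>.json` holding the pixel size and the gray-value scale; ROI and
#' cell masks are stored as companion binary TIFFs. The round trip is
#' exact for integer gray values.
#'
#' @param image a [labeled_image()].
#' @param path TIFF file path.
#' @return `read_image()` a `labeled_image`; `write_image()` the path,
#'   invisibly.
#' @export
write_image <- function(image, path) {
  scale <- 65535
  if (max(image$pixels) > scale)
    stop("gray values exceed the 16-bit range", call. = FALSE)
  tiff::writeTIFF(image$pixels / scale, path, bits.per.sample = 16L)
  for (nm in names(image$rois))
    tiff::writeTIFF(image$rois[[nm]] * 1, mask_path(path, "roi", nm),
                    bits.per.sample = 8L)
  for (i in seq_along(image$cell_masks %||% list()))
    tiff::writeTIFF(image$cell_masks[[i]] * 1,
                    mask_path(path, "cell", sprintf("%03d", i)),
                    bits.per.sample = 8L)
  jsonlite::write_json(
    list(pixel_size_mm = image$pixel_size_mm, scale = scale,
         rois = as.list(names(image$rois)),
         n_cell_masks = length(image$cell_masks %||% list())),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

mask_path <- function(path, kind, nm) {
  sub("\\.tiff?$", sprintf("_%s_%s.tif", kind, gsub("[^A-Za-z0-9]+", "-", nm)),
      path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  px <- round(tiff::readTIFF(path) * meta$scale)
  rois <- stats::setNames(lapply(meta$rois, function(nm)
    tiff::readTIFF(mask_path(path, "roi", nm)) > 0.5), unlist(meta$rois))
  cm <- if (meta$n_cell_masks > 0)
    lapply(seq_len(meta$n_cell_masks), function(i)
      tiff::readTIFF(mask_path(path, "cell", sprintf("%03d", i))) > 0.5)
  labeled_image(px, meta$pixel_size_mm, rois = rois, cell_masks = cm)
}

#' Read and write photometry traces
#'
#' The trace is a TSV with columns `t_s`, `f470` and optionally `f410`;
#' events are a one-column TSV `event_s`.
#'
#' @param path,events_path file paths.
#' @param trace a [photometry_trace()].
#' @return `read_photometry()` a `photometry_trace`.
#' @export
write_photometry <- function(trace, path, events_path) {
  df <- data.frame(t_s = trace$t, f470 = trace$f470)
  if (!is.null(trace$f410)) df$f410 <- trace$f410
  write_tsv(df, path)
  write_tsv(data.frame(event_s = trace$events), events_path)
  invisible(path)
}

#' @rdname write_photometry
#' @export
read_photometry <- function(path, events_path) {
  df <- read_tsv(path)
  check_columns(df, c("t_s", "f470"), path)
  ev <- read_tsv(events_path)
  check_columns(ev, "event_s", events_path)
  photometry_trace(t = df$t_s, f470 = df$f470, f410 = df$f410,
                   events = ev$event_s,
                   fs = 1 / stats::median(diff(df$t_s)))
}

#' Read a generator configuration from YAML
#'
#' Parses a YAML document into a validated [synth_config()]. Unknown keys
#' and invalid values fail naming the offending field.
#'
#' @param path YAML file path.
#' @return A `synth_config`.
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  known <- names(formals(synth_config))
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (!is.null(doc$region_extent))
    doc$region_extent <- lapply(doc$region_extent, as.numeric)
  if (!is.null(doc$group_region_weights))
    doc$group_region_weights <- lapply(doc$group_region_weights, unlist)
  if (!is.null(doc$marker_probs)) doc$marker_probs <- unlist(doc$marker_probs)
  do.call(synth_config, doc)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a pipeline run: the command, the
#' configuration snapshot, the seeds, the MD5 digest of every written
#' table, the package version and a timestamp. Re-running with the same
#' configuration and seed reproduces byte-identical tables (the manifest's
#' own timestamp is the one field that differs).
#'
#' @param out_dir output directory.
#' @param command label of the command that produced the run.
#' @param config the `synth_config` used.
#' @param seed the global seed.
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(out_dir, command, config, seed) {
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  digests <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(digests) <- files
  jsonlite::write_json(
    list(command = command,
         config = unclass(config),
         seed = seed,
         files = digests,
         package_version = as.character(utils::packageVersion("ensembleatlas")),
         timestamp = format(Sys.time(), tz = "UTC")),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(file.path(out_dir, "manifest.json"))
}
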