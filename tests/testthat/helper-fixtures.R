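# Shared fixtures, built in code.

# a minimal hand-written cell table
make_cells <- function(section_ap_mm, x_mm, y_mm,
                       mouse_id = "m01", group = "g1",
                       markers = "cFos", area = 0.9) {
  n <- length(x_mm)
  structure(data.frame(mouse_id = rep_len(mouse_id, n),
                       group = rep_len(group, n),
                       section_ap_mm = rep_len(section_ap_mm, n),
                       x_mm = x_mm, y_mm = y_mm,
                       markers = rep_len(markers, n),
                       section_area_mm2 = rep_len(area, n),
                       stringsAsFactors = FALSE),
            class = c("section_cell_table", "data.frame"))
}

# uniform-weight (no region bias) configuration over the 20 input regions
unbiased_config <- function(...) {
  w <- stats::setNames(rep(1, length(vta_input_regions)), vta_input_regions)
  synth_config(group_region_weights = list("Mor-Ens" = w, "Shock-Ens" = w),
               ...)
}

# pool one group's mice into a single table (same substream layout as
# gen_cell_tables, restricted to one group)
gen_group_cells <- function(config, seed, group = "g") {
  tabs <- lapply(seq_len(config$n_mice_per_group), function(mi)
    gen_point_pattern(config,
                      seed = ensembleatlas:::derive_seed(seed, 100L + mi),
                      mouse_id = sprintf("m%02d", mi), group = group))
  out <- do.call(rbind, lapply(tabs, as.data.frame))
  structure(out, class = c("section_cell_table", "data.frame"))
}
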