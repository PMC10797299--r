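# ensembleatlas

Quantitative analysis of activity-tagged neuronal ensembles.

Activity-dependent labeling (immediate-early-gene driven, e.g. c-Fos/RAM
tagging) marks the ensemble of neurons recruited by a specific
experience — a morphine injection, a foot-shock session, a home-cage
control. Comparing such ensembles within a region like the ventral
tegmental area (VTA) requires a chain of quantitative analyses that are
usually scattered across ImageJ macros and ad-hoc scripts. This package
implements that chain as one tested R pipeline, together with
synthetic-data generators that produce every input with known ground
truth, so each stage can be validated without any external data.

## What it computes

**Spatial statistics of labeled cells.** Per-mouse anterior–posterior
profiles (cells/mm² and fractions per 0.1 mm slab), mediolateral
profiles over |x| bins (0–0.3, 0.3–0.6, 0.6+ mm), distances from the
per-section ventral landmark with empirical CDFs, and paired-cell
distances: n random distinct within-section pairs (default 1000),
compared between groups with the two-sample Kolmogorov–Smirnov test,
D = sup|ECDF_a − ECDF_b|.

**Background-relative image quantification.** Background = median of a
signal-free ROI; signal = pixels strictly above k × background (k = 3
for axonal signal, k = 1.5 for PLA puncta); cells = 8-connected
components above a minimum area; per-region supra-threshold
arborization area (mm²) and integrated density; per-cell integrated
intensity within outline masks.

**Connectivity indexes**, all per mouse: normalized input index
count_r / Σ count (sums to 1); arborization per neuron
area_r / N_EGFP(VTA); axon density ID_r / ID_VTA; density fraction
ID_r / Σ_targets ID (VTA excluded from the denominator — it is the
source, not a target).

**Composite region ranking.** Per output index, a random-forest
classifier (500 trees, Gini splits) ranks regions by Mean Decrease
Gini; the composite report gives each region's frequency in the three
top-10 lists (0–3) and its mean Gini across indexes, plus a
seed-stability diagnostic.

**Event-locked photometry.** ΔF/F = (F − F₀)/F (as printed in the
source methodology; (F − F₀)/F₀ available as a switch) with F₀ the mean
of a pre-event window (2 s licking, 30 s tail suspension), epoching on
the native grid, first-k event filters, trapezoidal AUC over 0–5 s /
0–40 s windows, and signed peak responses; the isosbestic 410 nm
channel runs through the identical path as a motion control.

## A worked example

```r
library(ensembleatlas)

# a clustered and a dispersed ensemble, six mice each
cfg_clustered <- synth_config(pattern = "thomas", cluster_sd = 0.02)
cfg_dispersed <- synth_config()

pool <- function(cfg, seed0, grp) {
  tabs <- lapply(1:6, function(m)
    gen_point_pattern(cfg, seed = seed0 + m,
                      mouse_id = sprintf("m%02d", m), group = grp))
  do.call(rbind, lapply(tabs, as.data.frame))
}
mor   <- pool(cfg_clustered, 100, "Mor-Ens")
shock <- pool(cfg_dispersed, 200, "Shock-Ens")

a <- paired_distances(mor,   n_pairs = 1000, seed = 1)
b <- paired_distances(shock, n_pairs = 1000, seed = 2)
a
#> Distance sample (paired): group Mor-Ens, n = 1000, median 0.625 mm
b
#> Distance sample (paired): group Shock-Ens, n = 1000, median 0.692 mm
unlist(ecdf_compare(a, b))
#>            D            p          n_a          n_b 
#> 1.670000e-01 1.545208e-12 1.000000e+03 1.000000e+03
```

The clustered ensemble's paired distances are stochastically smaller
(median 0.62 vs 0.69 mm), and the KS test rejects emphatically: exactly
the signature that distinguishes a spatially clustered ensemble from a
dispersed one.

```r
# image quantification with known ground truth
img <- gen_section_image(synth_config(image_size = 128, blobs_per_image = 8,
                                      axon_area_px = 500), seed = 7)
bg <- estimate_background(img)            # median of the signal-free strip
cc <- count_cells(threshold_mask(img, bg, 3) & img$rois$cells,
                  min_area_px = 4)
c(planted = attr(img, "truth")$n_blobs, counted = cc$count,
  axon_px = sum(threshold_mask(img, bg, 3) & img$rois$axon))
#> planted counted axon_px 
#>       8       8     500
```

Eight planted cells are counted exactly, and the 3×-background rule
recovers the planted 500-pixel axon area pixel-for-pixel.

The whole pipeline — simulation, spatial statistics, image metrics,
connectivity indexes, ranking, photometry — runs from one call and one
seed, ending in a `manifest.json` with the MD5 digest of every output:

```r
out <- run_pipeline(synth_config(), "all", "my_run", seed = 1)
```

A thin command-line wrapper with the same subcommands is installed at
`exec/ensembleatlas`.

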