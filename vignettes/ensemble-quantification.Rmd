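---
title: "Quantifying activity-tagged neuronal ensembles: methods and design"
author: "ensembleatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying activity-tagged neuronal ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensembleatlas)
```

## The problem

Activity-dependent (immediate-early-gene driven) labeling marks the
*ensemble* of neurons recruited by a specific experience — for example the
VTA neurons activated by a morphine injection versus those activated by
foot shock. Comparing such ensembles raises a chain of quantitative
questions that this package answers with one tested code path each:

1. **Where are the tagged cells?** Axis profiles, distances from an
   anatomical landmark, and paired-cell distance distributions
   characterize spatial clustering and ventral/dorsal enrichment.
2. **How much signal is in an image?** Background-relative thresholding
   turns confocal sections into cell counts, supra-threshold areas, and
   integrated densities.
3. **How is the ensemble wired?** Ratio indexes summarize monosynaptic
   input counts and axonal output signal per brain region and mouse.
4. **Which regions discriminate two ensembles?** A random-forest Mean
   Decrease Gini ranking per output index, integrated across indexes.
5. **How does the ensemble respond in vivo?** Event-locked dF/F, AUC and
   peak metrics from two-channel fiber photometry.

Every analysis is exercised end-to-end on synthetic data with known
ground truth, generated by the package itself; no external data are
needed to validate any stage.

## The synthetic study

`synth_config()` fixes the simulated study conditions. The defaults
describe a mouse VTA-like setting: an AP × ML × DV box of
0.8 × 0.9 × 1.0 mm (AP −3.8 to −3.0 mm from bregma), 500 labeled cells
per mouse and 6 mice per group (group totals within the conventional
middle-VTA analysis window land in the few-hundreds range typical of
c-Fos counts), 20 input regions with multinomial count tables of 4000
input neurons per mouse, Poisson starter counts (mean 150), 256-px
section images at 2 µm/px with Gaussian cell blobs (radius 4 px, peak
amplitude 100 gray levels over an N(20, 2) background), and 100 Hz
photometry with 10% dF/F transients decaying with τ = 2 s.

Two spatial point processes are provided. The dispersed null is a
binomial (uniform) process; the clustered alternative is a Thomas-type
process — Poisson parents at `cluster_rate` per mm³, isotropic Gaussian
offspring with standard deviation `cluster_sd`, total count fixed at
`n_cells`. The Thomas process was chosen because it is the minimal
standard clustered point process with a single interpretable clustering
knob. Ventral enrichment is modeled as an exponential density decay,
$f(d) \propto e^{-g d}$, in the distance $d$ from the ventral boundary;
the generators expose the analytic ventral-half mass
$(1-e^{-gH/2})/(1-e^{-gH})$ that the tests check against. The hemisphere
(sign of the ML coordinate) is attached to the *cluster*, not the cell:
a cluster lives on one side of the midline, which is what preserves
clustering in the 2D section coordinates.

What the generators deliberately do **not** emulate: viral spread and
tracing efficiency, overlapping nuclei (blobs are non-overlapping by
construction, because the segmentation contract is exact count
recovery), illumination fields, photobleaching, and hemodynamic or
motion artifacts in photometry (the 410 nm channel is baseline + noise
by construction). Passing tests therefore demonstrate correctness of
the *operators*, not robustness to every pathology of real microscopy
or photometry data.

## Spatial statistics

Cells live in per-section 2D coordinates (`x_mm` signed ML, `y_mm` DV),
with sections defined by binning AP into half-open 0.1 mm slabs
`[lo, hi)`. The AP profile reports per-mouse areal density
(count / summed section area) and the fraction of the mouse's total
count, which sums to 1 per mouse by construction; a mouse with zero
cells is reported missing, never as zero. The ML profile bins
$|x|$ (distance from midline) at 0, 0.3, 0.6 mm and reports per-section
percentages.

Paired-cell distances are sampled uniformly, without replacement within
a draw, from the pool of distinct unordered *within-section* pairs —
2D coordinates are only comparable within a section, so cross-section
"distances" would be geometrically meaningless. If fewer pairs exist
than requested, all pairs are returned and the achieved `n` is
reported. Cells are canonicalized (sorted by coordinates) before
pairing, making the draw invariant to row order at fixed seed. Distance
distributions are compared with the two-sample Kolmogorov–Smirnov test
(asymptotic p, `stats::ks.test`).

One statistical subtlety matters and is checked by the test suite: the
1000 sampled pairs share cells, so they are not independent
observations. When pairs are drawn from a single mouse
(≈500 cells, each cell in ≈4 pairs) the dependence measurably inflates
the KS type-I rate above its nominal 5%. Drawn at the group level —
pooling a group's mice before sampling, the design the analyses here
use, with each cell in well under one pair on average — the test is
calibrated (measured ≈4% at α = 0.05) while retaining essentially full
power (≈98% at α = 0.001) against the clustered alternative with
`cluster_sd` = 0.02 mm. Group-level pooling is therefore the supported
design for inference on paired distances.

## Image quantification

The background estimator is the **median** of a user-designated
signal-free ROI; the median resists contamination by stray bright
pixels, and on generated backgrounds with sd ≤ 10% of the mean it is
within 2% of the true mean. Thresholding is strict:
pixels with value $> k \times$ background are signal, with $k = 3$ for
axonal signal and $k = 1.5$ for PLA puncta. The multiplier is a plain
argument everywhere: the phrase "k times higher than background" is
genuinely ambiguous between $k\times$ and $(1+k)\times$, and the
conventional ImageJ-style reading ($k\times$, strict) is the default.

Cell counting is thresholding plus **8-connected component labeling**
with a minimum-area filter (default 4 px in the pipeline). The labeling
is implemented in the package as iterative minimum-label propagation,
because the contract is specifically 8-connectivity (diagonal-touching
pixels are one cell). Touching blobs count as one component — no
watershed splitting is attempted, since no principled splitting rule is
part of the contract; the generator's non-overlap guarantee is what
makes exact recovery testable. All region metrics (supra-threshold area
in mm², integrated density) are checked *exactly* against a naive
per-pixel double loop on 200 random images.

## Connectivity indexes

All four indexes are per-mouse ratios, computed per mouse first and
summarized across mice second:

* normalized input index: region count / total input count (sums to 1);
* arborization per neuron: region supra-threshold area / VTA EGFP⁺ cell
  count (mm²/cell);
* axon density: region integrated density / VTA integrated density
  (dimensionless);
* density fraction: region integrated density / summed density over all
  target regions (sums to 1). The VTA is the *source*, not a target, so
  its own intensity is excluded from the denominator; the reader
  (`read_signal_table`) carries the VTA reference as per-mouse columns
  precisely so this exclusion is structural, not a filtering step.

## Random-forest region ranking

Each output index yields a mice × regions feature table with the group
as class label. `gini_importance()` trains a
`randomForest::randomForest` classifier (500 trees,
mtry = ⌊√p⌋, unlimited depth — the R randomForest conventions, since no
hyperparameters are part of the contract) and returns the Mean Decrease
Gini per region. Two implementation details were forced by measurement:
the forest is *not* invariant to class-level order under a fixed seed,
so the wrapper sorts rows by mouse id and codes classes by first
occurrence, making results invariant to row permutations and to
renaming the groups; and the forest does not terminate on an
all-constant feature matrix, so the no-informative-split case
short-circuits to all-zero importances (which is also the correct
answer).

The composite ranking takes the top 10 regions per index and reports,
per region, the *frequency* (number of indexes in whose top-10 it
appears, 0–3) and the *mean Gini across all three indexes* — averaging
over all indexes rather than only those where the region made the
top-10, because conditioning the average on top-10 membership would
inflate near-threshold regions; the unconditional mean is the more
conservative reading of an "average Mean Decrease Gini". Ties at the
top-k boundary break by (Gini descending, region name ascending), and
the rule is recorded in the result. With 4–6 mice per class the
out-of-bag error is reported for diagnostics but is never an acceptance
surface, and `rank_stability()` quantifies how often each region tops
the composite ranking across forest seeds.

The planted-effect validation multiplies one region's mean signal by 6
in one group at log-normal dispersion 0.2, giving a population
standardized group difference of ≈5.8 (well above 3) in each derived
index; the composite ranking recovers that region with frequency 3 and
top rank in ≈98% of seeds, while under pure noise the top-1 region is
uniform over the vocabulary (chi-square goodness of fit).

## Photometry

dF/F follows the formula $(F - F_0)/F$ with $F_0$ the mean of the
pre-event window of the same channel — implemented *as printed* in the
source methodology, because silently "correcting" it would make results
untraceable; the conventional $(F - F_0)/F_0$ is an explicit
`variant` switch. The printed denominator can be zero at a sample;
those samples are reported missing with a logged count rather than
failing the run. Both variants are invariant to rescaling the raw
fluorescence by a positive constant. Baseline windows default to 2 s
pre-event (consummatory licking) and 30 s (tail suspension); epochs are
half-open `[pre, post)` on the native grid, so a (−2, 5) s window at
100 Hz is exactly 700 samples; events whose window leaves the recording
are dropped with a notice, and a first-k filter (k = 4 for licks)
selects the conventionally analyzed events. AUC is the trapezoidal
integral on the native grid (no resampling, hence exact additivity over
adjacent windows), and peaks are signed extrema with a minimum option
for suppression analyses. No low-pass filtering or isosbestic
regression is applied; the 410 nm channel is simply run through the
identical pipeline as the motion control.

## Numerical choices and degenerate inputs

* All randomness flows from explicit seeds; generators restore the
  caller's RNG state, and per-mouse substreams use fixed offsets so
  adding a mouse never changes earlier mice.
* Zero denominators are contract violations (VTA references, positive
  by invariant) or missing values (zero total counts, zero base-marker
  cells), never silent zeros.
* Blob placement uses bounded rejection sampling with restarts and
  fails explicitly when the requested count cannot be placed without
  overlap.
* Half-open binning `[lo, hi)` is used for AP slabs, ML bins and epoch
  windows alike; AUC windows `[a, b]` are closed so that adjacent
  windows share their boundary sample exactly.
* Fractions are checked to sum to 1 within 1e-9; AUC additivity to
  1e-12.

## Problem sizes

The validation suite runs, per property: 100 random count/signal tables
for normalization; 200 random 64×64 images against the per-pixel
oracle; 100 seeded 128-px images for exact count recovery; 200
clustered-vs-dispersed and 400 matched-null KS runs at 1000 pairs
(six 500-cell mice per group per run); 100 planted-effect and 200
pure-noise ranking runs (500-tree forests, 20 regions, 12 mice); and a
double end-to-end pipeline run for byte-identical reproducibility.

## Known limitations

* The KS calibration statement applies to group-pooled pair sampling;
  single-mouse sampling with n_pairs comparable to the cell count is
  anticonservative (see above) and should be interpreted descriptively.
* Touching cells are counted as one; the counter is exact only for
  non-overlapping somata.
* The ranking is a discrimination screen on a handful of mice, not a
  calibrated hypothesis test; use `rank_stability()` before reading
  anything into an individual rank.
* The per-seed ordering of clustered vs dispersed *median* pair
  distance holds in a clear majority of seeds but not every seed at
  these study sizes; distribution-level comparison (KS) is the
  supported inference.
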