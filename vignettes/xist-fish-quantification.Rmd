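---
title: "Quantifying Xist RNA-FISH, GATA6 translocation and Flow-FISH data"
author: "xistquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Xist RNA-FISH, GATA6 translocation and Flow-FISH data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xistquant)
```

## The measurement problem

X-chromosome inactivation begins when the long non-coding RNA Xist
accumulates as a "cloud" on the X chromosome. Experiments that probe how
transcription factors such as GATA6 control this switch produce four
kinds of quantitative raw data, all covered by this package:

1. **IF-RNA-FISH images of cultured cells** — widefield z-stacks with a
   DNA stain (DAPI), an immunofluorescence channel for HA-tagged GATA6,
   and an RNA-FISH channel for Xist. The questions are *how nuclear* the
   tagged factor is (nuclear translocation) and *how much* Xist signal
   each nucleus carries.
2. **RNA-FISH images of eight-cell embryos** — confocal stacks with
   Xist and a nascent-transcript probe for the X-linked gene *Huwe1*,
   which is not yet silenced at this stage: female (XX) nuclei show two
   Huwe1 foci, male (XY) nuclei one. Only female embryos are analysed.
3. **Flow-FISH event tables** — per-cell Xist fluorescence read by flow
   cytometry, gated against a non-expressing control.
4. **Genomic qPCR panels** — Cq values used to map whether a locus lies
   inside a single-copy YAC transgene (two copies in the transgenic XY
   line, dosage ratio ~2) or outside it (one copy, ratio ~1).

Because the raw microscope data behind published figures are not
reproducible at desk scale, the package ships a seeded synthetic-data
generator with full ground truth. All pipeline claims in this vignette
are backed by parameter-recovery tests in `tests/testthat/`, which are
the only empirical results we state.

## Image analysis chain

### Projection and segmentation

Z-stacks are maximum-intensity projected (`max_project()`); all 2D
analysis runs on the projection. The stack geometry helper
`axial_extent(n, dz)` returns `(n - 1) * dz`, e.g. 62 slices at 0.23 um
span 14.03 um — slightly more than an adherent ES cell is tall.

Nuclei are detected from the DNA channel by the classical chain in
`segment_nuclei()`:

smooth (Gaussian, `sigma`) → Otsu threshold (256-bin between-class
variance; foreground strictly above) → hole filling → optional binary
dilation → distance-transform watershed with seed merging radius
`seed_separation`.

Objects are then filtered by area and circularity
(`filter_objects()`), where circularity is
`sqrt(4 * area / (pi * FeretMax^2))` — 1 for a disc, smaller for
elongated or fused objects. The conventional acceptance windows are
50–300 um² with circularity 0.5–1 for cultured cells and 100–450 um²
with 0.7–1 for embryo nuclei. Both intervals are closed; the maximal
Feret diameter is computed over pixel-corner coordinates so that thin
objects keep a finite, non-zero circularity (a single pixel has Feret
diameter `sqrt(2)` pixel widths).

Defaults: `sigma = 2` px, `dilate = 0`, `seed_separation = 10` px,
watershed `tolerance = 1`. We calibrated the dilation default on the
synthetic fixture: with 0 iterations segmented areas match the planted
ellipses to within ±0.4%, while a single 3×3 dilation inflates them by
7–12% (into the cytoplasmic halo) and would push measured
nuclear-to-cytoplasmic ratios off target. Dilation remains available
for noisy real data where the Otsu mask underfills nuclei.

### Nuclear-to-cytoplasmic ratio

`cytoplasm_ring()` draws a peri-nuclear ring (default width 30 px,
i.e. 2.64 um at 0.088 um/px) as a surrogate for the cytoplasm: pixels
within the ring width of the nucleus, excluding every nucleus, with
contested pixels (reachable from two rings) assigned to the nucleus
with the nearer boundary. This shrinks rings between crowded nuclei
rather than letting them overlap; a nucleus walled in by neighbours
gets a near-empty ring and its record is flagged (`min_ring_px`,
default 50) instead of silently producing a bad ratio.
`nuc_cyt_ratio()` is then simply mean(nucleus) / mean(ring) of the
GATA6-HA channel — the proxy for nuclear translocation.

### Cloud and focus detection

`detect_clouds()` runs: Gaussian smooth (1 px) → rolling-ball
background subtraction → fixed intensity threshold → connected
components → optional circularity filter [0.5, 1] (cell mode only; the
embryo convention applies none) → assignment of each component to the
nucleus containing its intensity-weighted centroid; components outside
all nuclei are discarded. The rolling-ball background (radius 20 px) is
the grayscale morphological opening with a flat disc — the surface a
ball of that radius can reach from below — so structures narrower than
the ball survive and the output is non-negative.

Huwe1 nascent-transcript foci use the same chain with a 2 px minimum
area and no circularity filter (`huwe1_counts()`); embryo sex is called
from the median per-nucleus count (`embryo_sex()`): 2 → female,
1 → male, anything else → ambiguous. Sexing by eye is the field's
practice; automating it through the spot detector is an extension of
this package, and the median rule makes the call robust to a single
mis-counted nucleus.

Two inclusion rules are enforced by `apply_exclusions()` with a full
audit trail: cell mode drops cells with more than two detected Xist
objects (segmentation errors), embryo mode drops nuclei without a Huwe1
signal. Retained plus excluded always reconciles with the input count.

**The fixed threshold.** The detection threshold is a config value per
experiment, as it is in practice. On synthetic data
`suggest_threshold()` derives it from the planted blob shape: a 2D
Gaussian of integrated intensity *I* and radius sigma has peak
`I / (2 pi sigma_px^2)`, and a threshold at fraction *f* of the peak
captures exactly `1 - f` of the blob mass, so the default `f = 0.03`
keeps ~97% of the planted intensity inside the mask while sitting far
above the smoothed noise floor. When several conditions share one
threshold it is derived from the dimmest condition
(`scale` argument), which keeps the captured fraction comparable across
conditions.

**Summed intensity.** Per-cloud intensity is summed over the
*unsmoothed* background-subtracted channel by default
(`intensity_on = "bgsub"`); raw-channel summation is available by flag.
Background-subtracted summation makes the measure invariant to additive
background, at the price of a small (<5%) truncation of blob tails
outside the detected mask.

## Statistics

Group comparisons use the two-sided Wilcoxon rank-sum test
(`wilcoxon_rank_sum()`): exact enumeration when both groups have at
most 10 observations and no ties, otherwise the normal approximation
with tie and continuity correction. Paired and one-sample t-tests and
Benjamini–Hochberg adjustment mirror the conventions used for
qPCR/Flow-FISH replicate comparisons. Box summaries
(`boxplot_summary()`) use linearly interpolated quartiles with whiskers
at the most extreme data within 1.5 IQR of the box. Flow gating
(`percentile_gate()`) places the positivity threshold at the linearly
interpolated 99th percentile of the undifferentiated control, calls
events strictly above it positive, and reports the geometric mean of
the positive fraction minus the control geometric mean
(`corrected_geomean()`); `top_fraction()` reproduces top-15% sorting.
The cell pipeline groups cells by detected Xist-signal count and
compares per-group nuc:cyt ratios pairwise; the embryo pipeline
compares per-cell summed Xist intensities between conditions, treating
cells (pooled across embryos) as the unit, which matches how such
figures annotate n; per-embryo aggregation can be done on the returned
cell table if embryos are preferred as units.

qPCR dosage ratios assume perfect doubling (efficiency 2.0): relative
quantity `2^-(Cq_target - Cq_norm)` within each line, then the
transgenic:reference ratio. The decision band for "~2 vs ~1" is a
package convention: internal at ratio >= 1.5, external at <= 1.35,
indeterminate in between — a deliberate buffer rather than a hard
binary, configurable in `classify_position()`.

## The synthetic-data generator

`generate_cell_field()` / `generate_embryo_field()` render, per field:

- elliptical nuclei (uniform interior intensity) with areas,
  eccentricities and minimum centroid spacing drawn from the config;
  an optional `touching_fraction` places close pairs to exercise
  watershed splitting;
- a cytoplasmic halo around each nucleus; the GATA6 channel is built so
  that the nuclear mean equals exactly `nuc_cyt_ratio_true` times the
  halo mean before noise;
- 0–3 Xist clouds per nucleus (configurable probabilities) as
  sum-normalised Gaussian blobs, so each planted integrated intensity
  is conserved in the rendered image up to 4-sigma window truncation
  (<0.04%); cloud intensity is multiplied by `condition_scale`
  (1 = control, e.g. 0.2 for a knock-out with 5-fold reduced Xist);
- 1–2 Huwe1 point foci per nucleus encoding sex (embryo mode);
- additive background and Gaussian noise, clipped at zero.

Determinism: a single seed makes fields bit-identical, and noise is
drawn before any blob-position sampling with inverse-CDF cloud-count
sampling (one uniform per nucleus), so the DNA and GATA6 channels are
invariant to cloud settings at a fixed seed — a property the
channel-independence tests rely on.

Defaults follow the acquisition geometry of the experiments being
emulated: 0.088 um/px for widefield cell imaging (back-derived from the
30 px = 2.64 um ring) and 0.07 um/px for confocal embryo imaging.
Intensity levels, cloud-count probabilities and noise levels are not
published per cell, so the defaults (halo mean 100, nucleus:halo DNA
contrast 15:1, cloud integrated intensity 2e4, background 10, noise sd
2) are conventions chosen once to resemble 12-bit fluorescence data,
not fits. Clouds within one nucleus are kept >= 10 sigma apart:
separate Xist territories in projection are visually distinct, and this
guarantees the fixed-threshold detector never fuses two planted blobs
(the saddle between two blobs at that distance is far below the 3%-peak
threshold).

What the generator does **not** emulate: chromatin texture, optical
PSF / 3D cloud structure (stacks are emulated by slicing a blurred 2D
field), channel bleed-through, Poisson photon statistics (the chain is
threshold-based; additive Gaussian noise suffices to probe it), or
uneven illumination. Passing recovery tests therefore validate the
operator chain, not performance on adverse real-world imaging.

## Problem sizes used by the test suite

Simulation-based tests run at 0.25 um/px on 512 px (cell) and 448 px
(embryo) fields, with the ring width scaled to the same physical
2.64 um (11 px). This coarser grid keeps a nucleus tens rather than
hundreds of pixels across, which is the regime the operators care
about, while letting the whole recovery suite (48 nuclei for ratio
recovery, 30 for cloud-count recovery, >= 200 cells per condition for
the intensity-scale contrast, 20 five-vs-five embryo simulations) run
in a few minutes. Generator *defaults* keep the published pixel sizes.

## A worked example

```{r example, eval = FALSE}
cfg <- synth_field_config(mode = "cell", image_shape = c(512L, 512L),
                          pixel_size = 0.25, n_nuclei = 12,
                          nucleus_area_range = c(80, 250),
                          min_centroid_spacing = 24,
                          nuc_cyt_ratio_true = 3, noise_sd = 5, seed = 7)
field <- generate_cell_field(cfg)
rc <- run_config("cell",
                 cloud_threshold = suggest_threshold(cfg, "cloud"),
                 ring_width_px = 11, seed = 7)
res <- run_cell_analysis(list(field), rc)
head(res$retained[, c("nucleus", "nuc_cyt_ratio", "n_xist_clouds",
                      "xist_summed_intensity")])
res$group_summaries
res$tests
```

## Known limitations

- Segmentation is the classical smooth/Otsu/watershed chain; the
  trained pixel classifiers used by commercial software on hard
  real-world data are out of scope, so heavily textured or dim nuclei
  may need parameter tuning (`segment_params()`).
- Cloud-to-nucleus assignment is by intensity-weighted centroid
  containment; a cloud straddling a nucleus boundary is attributed to
  exactly one nucleus.
- The Wilcoxon exact path requires tie-free data; measured intensities
  effectively never tie, but heavily rounded inputs will silently use
  the corrected normal approximation (reported in the result's
  `method` field).
- qPCR classification assumes amplification efficiency 2.0; panels
  with poor primer efficiency need external calibration before the
  dosage-ratio rule applies.
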