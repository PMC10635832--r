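# xistquant

Automated quantification of X-chromosome inactivation experiments:
RNA-FISH imaging of Xist clouds in cultured cells and preimplantation
embryos, immunofluorescence-based nuclear-translocation measurement,
Flow-FISH gating, and qPCR transgene-boundary mapping — together with a
seeded synthetic-data generator with full ground truth, so every
analysis step can be benchmarked by parameter recovery.

## Who this is for

Labs quantifying Xist upregulation (or any nuclear RNA "cloud"
phenotype) from multi-channel fluorescence images, and anyone needing a
tested, scriptable replacement for point-and-click image-analysis
pipelines: segment nuclei, measure per-nucleus signals, apply the
field's inclusion rules, and run the standard statistics, end to end
and reproducibly.

## What it computes

- **Nucleus segmentation** (`segment_nuclei`): Gaussian smooth → Otsu
  threshold → hole fill → optional dilation → distance-transform
  watershed; objects filtered by area and circularity
  `sqrt(4·area / (π·FeretMax²))` (cell window 50–300 µm², 0.5–1;
  embryo window 100–450 µm², 0.7–1).
- **Nuclear translocation** (`cytoplasm_ring`, `nuc_cyt_ratio`): mean
  nuclear over mean peri-nuclear-ring intensity (ring width 30 px =
  2.64 µm at 0.088 µm/px), with contested ring pixels assigned to the
  nearer nucleus.
- **Xist cloud detection** (`rolling_ball`, `detect_clouds`,
  `summed_intensity`): smooth → rolling-ball background subtraction
  (radius 20 px) → fixed threshold → per-nucleus cloud counts and
  summed intensities; cells with more than two Xist objects are
  excluded with an audit entry.
- **Embryo sexing** (`huwe1_counts`, `embryo_sex`): Huwe1
  nascent-transcript foci — two per nucleus in females, one in males;
  only female embryos are analysed, nuclei without a Huwe1 signal are
  excluded.
- **Flow-FISH gating** (`percentile_gate`, `corrected_geomean`,
  `top_fraction`): 99th-percentile gate on a non-expressing control,
  percent positive, background-corrected geometric mean, top-15%
  selection.
- **Transgene mapping** (`dosage_ratio`, `classify_position`):
  `2^-ΔCq` dosage ratios between a transgenic and a reference XY line,
  classifying loci as internal (~2) or external (~1) to a single-copy
  transgene.
- **Statistics** (`wilcoxon_rank_sum`, `paired_t_test`,
  `one_sample_t_test`, `bh_adjust`, `boxplot_summary`): the tests and
  summary conventions used for all group comparisons.
- **Pipelines** (`run_cell_analysis`, `run_embryo_analysis`):
  orchestrate the above per field, log every dropped record, and stamp
  outputs with a config hash and seed.

## Worked example

Simulate one field of cells with a planted nuclear:cytoplasmic GATA6
ratio of 3 and 5% noise, then run the full cell pipeline:

```r
library(xistquant)

cfg <- synth_field_config(mode = "cell", image_shape = c(512L, 512L),
                          pixel_size = 0.25, n_nuclei = 12,
                          nucleus_area_range = c(80, 250),
                          min_centroid_spacing = 24,
                          nuc_cyt_ratio_true = 3, noise_sd = 5, seed = 7)
field <- generate_cell_field(cfg)
rc <- run_config("cell", cloud_threshold = suggest_threshold(cfg, "cloud"),
                 ring_width_px = 11, seed = 7)
res <- run_cell_analysis(list(field), rc)
res$retained[1:4, c("nucleus", "nuc_cyt_ratio", "n_xist_clouds",
                    "xist_summed_intensity")]
#>   nucleus nuc_cyt_ratio n_xist_clouds xist_summed_intensity
#> 1       1      2.997725             0                  0.00
#> 2       2      2.992839             0                  0.00
#> 3       3      2.990149             2              41599.08
#> 4       4      2.990847             0                  0.00
```

All twelve nuclei are segmented; recovered ratios sit within 0.4% of
the planted 3.0, detected cloud counts equal the planted truth, and a
nucleus with two clouds of planted integrated intensity 20,000 each
reports a summed intensity of ~41,600 (within 5%, mask truncation plus
noise). An embryo comparison of 3 control vs 3 knock-down–like females
(`condition_scale = 0.2`) gives a median intensity ratio of 0.219 and a
two-sided Wilcoxon rank-sum p = 4.4e-07 on 24 vs 24 cells.

## Layout

```
R/                  implementation (generator, segmentation,
                    quantification, flow gating, qPCR, stats, pipeline)
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R  reference computation (JSON output)
vignettes/          methods vignette: models, parameters, design choices
```
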