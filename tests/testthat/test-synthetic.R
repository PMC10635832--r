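test_that("generated cell fields match their construction", {
  cfg <- quick_cell_config(n_nuclei = 5L, noise_sd = 0, seed = 1L)
  f <- generate_cell_field(cfg)
  expect_equal(nrow(f$truth$nuclei), 5L)
  expect_named(f$channels, c("DNA", "GATA6", "Xist"))
  # DNA channel has exactly 5 connected foreground components
  fg <- (f$channels$DNA$values > cfg$background_level) * 1
  comp <- EBImage::bwlabel(fg)
  expect_equal(max(comp), 5)
})

test_that("planted nuc:cyt ratio is exact before noise", {
  cfg <- quick_cell_config(n_nuclei = 6L, noise_sd = 0,
                           nuc_cyt_ratio_true = 3, seed = 2L)
  f <- generate_cell_field(cfg)
  gata <- f$channels$GATA6$values
  ps <- cfg$pixel_size
  halo_px <- cfg$cytoplasm_halo_width / ps
  for (i in seq_len(6)) {
    nuc <- f$truth$nuclei[i, ]
    # reconstruct the planted masks from the truth geometry
    nm <- matrix(FALSE, nrow(gata), ncol(gata))
    nm[xistquant:::ellipse_pixels(dim(gata), c(nuc$centroid_row, nuc$centroid_col),
                                  nuc$a_px, nuc$b_px, nuc$theta)] <- TRUE
    hm <- matrix(FALSE, nrow(gata), ncol(gata))
    hm[xistquant:::ellipse_pixels(dim(gata), c(nuc$centroid_row, nuc$centroid_col),
                                  nuc$a_px, nuc$b_px, nuc$theta,
                                  grow = halo_px)] <- TRUE
    hm <- hm & !nm
    expect_equal(mean(gata[nm]) / mean(gata[hm]), 3, tolerance = 1e-6)
  }
})

test_that("forcing three clouds per nucleus plants exactly three", {
  cfg <- quick_cell_config(n_nuclei = 5L,
                           cloud_count_probs = c(0, 0, 0, 1), seed = 3L)
  f <- generate_cell_field(cfg)
  expect_true(all(f$truth$nuclei$true_cloud_count == 3L))
  expect_equal(nrow(f$truth$clouds), 15L)
})

test_that("identical config and seed give bit-identical output", {
  cfg <- quick_cell_config(n_nuclei = 6L, seed = 11L)
  f1 <- generate_cell_field(cfg)
  f2 <- generate_cell_field(cfg)
  expect_identical(lapply(f1$channels, `[[`, "values"),
                   lapply(f2$channels, `[[`, "values"))
  expect_identical(f1$truth$nuclei, f2$truth$nuclei)
  expect_identical(f1$truth$clouds, f2$truth$clouds)
})

test_that("cloud channel settings leave DNA and GATA6 unchanged", {
  base <- quick_cell_config(n_nuclei = 6L, seed = 12L)
  none <- quick_cell_config(n_nuclei = 6L, seed = 12L,
                            cloud_count_probs = c(1, 0, 0, 0))
  f1 <- generate_cell_field(base)
  f2 <- generate_cell_field(none)
  expect_identical(f1$channels$DNA$values, f2$channels$DNA$values)
  expect_identical(f1$channels$GATA6$values, f2$channels$GATA6$values)
  expect_equal(nrow(f2$truth$clouds), 0L)
})

test_that("rendered cloud intensity is conserved within 0.1%", {
  cfg <- quick_cell_config(n_nuclei = 8L, noise_sd = 0, background_level = 0,
                           cloud_count_probs = c(0, 0.3, 0.5, 0.2), seed = 4L)
  f <- generate_cell_field(cfg)
  total <- sum(f$channels$Xist$values)
  expect_equal(total, sum(f$truth$clouds$intensity), tolerance = 1e-3)
})

test_that("impossible placement signals an error with the achieved count", {
  cfg <- quick_cell_config(n_nuclei = 40L, min_centroid_spacing = 40,
                           seed = 5L)
  err <- tryCatch(generate_cell_field(cfg), error = function(e) e)
  expect_s3_class(err, "xq_placement_error")
  expect_true(err$placed >= 1L && err$placed < 40L)
})

test_that("embryo fields encode sex in the Huwe1 truth and have 8 nuclei", {
  cfg <- quick_embryo_config(n_nuclei = 3L, seed = 6L)
  ff <- generate_embryo_field(cfg, sex = "female")
  fm <- generate_embryo_field(cfg, sex = "male")
  expect_equal(nrow(ff$truth$nuclei), 8L)  # n_nuclei forced to 8
  expect_true(all(ff$truth$nuclei$true_huwe1_count == 2L))
  expect_true(all(fm$truth$nuclei$true_huwe1_count == 1L))
  expect_named(ff$channels, c("DNA", "Xist", "Huwe1"))
})

test_that("condition_scale scales the noise-free Xist channel linearly", {
  mk <- function(scale) quick_embryo_config(noise_sd = 0, background_level = 0,
                                            condition_scale = scale, seed = 7L)
  f1 <- generate_embryo_field(mk(1), "female")
  f2 <- generate_embryo_field(mk(0.2), "female")
  expect_equal(sum(f2$channels$Xist$values) / sum(f1$channels$Xist$values),
               0.2, tolerance = 1e-6)
})

test_that("flow generator matches its sampling model", {
  cfg <- flow_sim_config(n_events = 10000L, expressing_fraction = 0.5,
                         expressing_fold_change = 100, seed = 8L)
  ctrl <- generate_flow_sample(cfg, is_control = TRUE)
  expect_equal(ctrl$n_events, 10000L)
  # expressing_fraction = 0 reproduces the control exactly at the same seed
  cfg0 <- flow_sim_config(n_events = 10000L, expressing_fraction = 0,
                          expressing_fold_change = 100, seed = 8L)
  expect_identical(generate_flow_sample(cfg0)$events, ctrl$events)
  # Monte-Carlo check of the planted fold change
  s <- generate_flow_sample(cfg)
  hi <- s$events[1:5000]; lo <- s$events[5001:10000]
  expect_equal(median(hi) / median(lo), 100, tolerance = 0.2)
})

test_that("config validation rejects malformed inputs", {
  expect_error(quick_cell_config(cloud_count_probs = c(0.5, 0.5, 0.5, 0)),
               "summing to 1")
  expect_error(quick_cell_config(nucleus_eccentricity_range = c(0.5, 1.2)),
               "eccentricity")
  expect_error(quick_cell_config(nucleus_area_range = c(300, 100)),
               "area_range")
  expect_error(flow_sim_config(expressing_fraction = 1.5), "expressing_fraction")
})
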