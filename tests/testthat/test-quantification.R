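test_that("isolated ring matches a brute-force distance computation", {
  shape <- c(128, 128)
  core <- disc_mask(shape, 64, 64, 20)
  lm <- label_map(core * 1L, 0.088)
  width <- 30
  ring <- cytoplasm_ring(lm, 1L, width)
  # oracle: pixels within 'width' of the nearest nucleus pixel (Euclidean)
  px <- which(core, arr.ind = TRUE)
  all_px <- as.matrix(expand.grid(r = 1:shape[1], c = 1:shape[2]))
  d2 <- matrix(Inf, shape[1], shape[2])
  for (k in seq_len(nrow(px)))
    d2 <- pmin(d2, matrix((all_px[, 1] - px[k, 1])^2 +
                            (all_px[, 2] - px[k, 2])^2, shape[1], shape[2]))
  oracle <- !core & sqrt(d2) <= width
  expect_equal(which(ring), which(oracle))
})

test_that("rings of close nuclei are disjoint and avoid all nuclei", {
  shape <- c(160, 160)
  lab <- disc_mask(shape, 70, 80, 18) * 1L
  lab[disc_mask(shape, 116, 80, 18) & lab == 0L] <- 2L  # 10 px gap
  lm <- label_map(lab, 0.088)
  r1 <- cytoplasm_ring(lm, 1L, 30)
  r2 <- cytoplasm_ring(lm, 2L, 30)
  expect_false(any(r1 & r2))
  expect_false(any((r1 | r2) & lab > 0))
  # contested pixels go to the nearer boundary: the midline between the
  # two discs splits ownership
  expect_true(any(r1) && any(r2))
})

test_that("a nucleus walled in by neighbours has a near-empty ring", {
  shape <- c(200, 200)
  lab <- matrix(0L, shape[1], shape[2])
  centers <- expand.grid(r = c(70, 100, 130), c = c(70, 100, 130))
  # centre disc first so it gets label 1
  ord <- order((centers$r - 100)^2 + (centers$c - 100)^2)
  for (i in seq_along(ord)) {
    m <- disc_mask(shape, centers$r[ord[i]], centers$c[ord[i]], 15)
    lab[m & lab == 0L] <- i
  }
  lm <- label_map(lab, 0.088)
  iso <- sum(cytoplasm_ring(label_map(disc_mask(shape, 100, 100, 15) * 1L,
                                      0.088), 1L, 30))
  ring <- tryCatch(cytoplasm_ring(lm, 1L, 30), xq_empty_ring = function(e) NULL)
  n_ring <- if (is.null(ring)) 0L else attr(ring, "n_px")
  expect_lt(n_ring, 0.1 * iso)
})

test_that("nuc:cyt ratio is the ratio of mask means", {
  img <- pixel_image(matrix(10, 20, 20), 0.1)
  nm <- matrix(FALSE, 20, 20); nm[8:12, 8:12] <- TRUE
  rm_ <- matrix(FALSE, 20, 20); rm_[1:3, ] <- TRUE
  img$values[nm] <- 30
  expect_equal(nuc_cyt_ratio(img, nm, rm_), 3.0)
  uni <- pixel_image(matrix(42, 20, 20), 0.1)
  expect_equal(nuc_cyt_ratio(uni, nm, rm_), 1.0)
  zero <- pixel_image(matrix(0, 20, 20), 0.1)
  expect_warning(r <- nuc_cyt_ratio(zero, nm, rm_), "zero")
  expect_true(is.na(r))
  expect_error(nuc_cyt_ratio(img, matrix(FALSE, 20, 20), rm_), "empty")
})

test_that("rolling ball removes smooth background and keeps spikes", {
  const <- pixel_image(matrix(50, 80, 80), 0.1)
  expect_true(all(rolling_ball(const, 20)$values == 0))
  # isolated 3-px spike of height h on constant background survives
  h <- 100
  v <- matrix(50, 80, 80); v[40, 40:42] <- 50 + h
  out <- rolling_ball(pixel_image(v, 0.1), 20)
  expect_gte(max(out$values[40, 40:42]), 0.9 * h)
  # subtraction of a non-negative background never increases the total
  set.seed(5)
  rnd <- pixel_image(matrix(runif(80 * 80, 0, 100), 80, 80), 0.1)
  out2 <- rolling_ball(rnd, 10)
  expect_lte(sum(out2$values), sum(rnd$values))
  expect_true(all(out2$values >= 0))
  expect_error(rolling_ball(pixel_image(matrix(1:4 * 1.0, 2, 2), 0.1), 20),
               "larger than the image")
})

test_that("every planted cloud is found on a noise-free field", {
  cfg <- quick_cell_config(n_nuclei = 8L, noise_sd = 0,
                           cloud_count_probs = c(0, 1, 0, 0), seed = 41L)
  f <- generate_cell_field(cfg)
  lm <- segment_nuclei(f$channels$DNA)
  thr <- suggest_threshold(cfg, "cloud")
  cl <- detect_clouds(f$channels$Xist, lm, cloud_params(thr))
  expect_equal(nrow(cl), 8L)
  expect_setequal(cl$nucleus, 1:8)
  # threshold above the maximum intensity finds nothing
  none <- detect_clouds(f$channels$Xist, lm,
                        cloud_params(max(f$channels$Xist$values) + 1))
  expect_equal(nrow(none), 0L)
})

test_that("summed intensity is additive and recovers planted intensity", {
  img <- pixel_image(matrix(0, 30, 30), 0.1)
  m1 <- matrix(FALSE, 30, 30); m1[2:3, 2:6] <- TRUE
  img$values[m1] <- 2
  expect_equal(summed_intensity(img, m1), 20)
  m2 <- matrix(FALSE, 30, 30); m2[20:24, 20] <- TRUE
  img$values[m2] <- 7
  expect_equal(summed_intensity(img, m1 | m2),
               summed_intensity(img, m1) + summed_intensity(img, m2))
  expect_error(summed_intensity(img, matrix(FALSE, 30, 30)), "empty")

  # noise-free recovery of the planted integrated intensity within 5%
  cfg <- quick_cell_config(n_nuclei = 6L, noise_sd = 0,
                           cloud_count_probs = c(0, 1, 0, 0), seed = 42L)
  f <- generate_cell_field(cfg)
  lm <- segment_nuclei(f$channels$DNA)
  cl <- detect_clouds(f$channels$Xist, lm,
                      cloud_params(suggest_threshold(cfg, "cloud")))
  expect_equal(nrow(cl), 6L)
  planted <- cfg$cloud_integrated_intensity
  expect_true(all(abs(cl$summed_intensity - planted) / planted < 0.05))
})

test_that("measured summed intensity is monotone in planted intensity", {
  prev <- -Inf
  for (inten in c(5e3, 2e4, 8e4)) {
    cfg <- quick_cell_config(n_nuclei = 4L, noise_sd = 0,
                             cloud_integrated_intensity = inten,
                             cloud_count_probs = c(0, 1, 0, 0), seed = 43L)
    f <- generate_cell_field(cfg)
    lm <- segment_nuclei(f$channels$DNA)
    cl <- detect_clouds(f$channels$Xist, lm,
                        cloud_params(suggest_threshold(cfg, "cloud")))
    tot <- sum(cl$summed_intensity)
    expect_gt(tot, prev)
    prev <- tot
  }
})

test_that("huwe1 counting separates female and male fixtures", {
  for (sex in c("female", "male")) {
    cfg <- quick_embryo_config(seed = 44L)
    f <- generate_embryo_field(cfg, sex = sex)
    lm <- segment_nuclei(f$channels$DNA)
    sp <- cloud_params(suggest_threshold(cfg, "spot"), min_area_px = 2,
                       circ_range = NULL)
    counts <- huwe1_counts(f$channels$Huwe1, lm, sp)
    expect_true(all(counts$huwe1_count == if (sex == "female") 2L else 1L))
    # single-nucleus interface agrees
    nm <- lm$labels == 1L
    expect_equal(count_huwe1(f$channels$Huwe1, nm, sp),
                 counts$huwe1_count[counts$nucleus == 1L])
  }
  # empty channel -> zero everywhere
  blank <- pixel_image(matrix(0, 64, 64), 0.25)
  lm0 <- label_map(disc_mask(c(64, 64), 32, 32, 10) * 1L, 0.25)
  sp0 <- cloud_params(5, min_area_px = 2, circ_range = NULL, ball_radius = 10)
  expect_equal(huwe1_counts(blank, lm0, sp0)$huwe1_count, 0L)
})

test_that("embryo sexing follows the median rule", {
  expect_equal(embryo_sex(rep(2L, 8)), "female")
  expect_equal(embryo_sex(rep(1L, 8)), "male")
  expect_equal(embryo_sex(c(2L, 2L, 1L, 1L)), "ambiguous")  # median 1.5
  expect_equal(embryo_sex(c(2L, 2L, 2L, 1L)), "female")
  expect_error(embryo_sex(integer(0)), "no nuclei")
})

test_that("exclusion rules drop the right records and reconcile counts", {
  cells <- data.frame(nucleus = 1:4, n_xist_clouds = c(0L, 2L, 3L, 5L))
  ex <- apply_exclusions(cells, "cell")
  expect_equal(ex$retained$nucleus, 1:2)  # 2 clouds retained (boundary)
  expect_equal(ex$audit$nucleus, 3:4)
  expect_true(all(ex$audit$reason == "more than two Xist objects"))
  expect_equal(nrow(ex$retained) + nrow(ex$audit), ex$n_input)

  emb <- data.frame(nucleus = 1:3, huwe1_count = c(0L, 1L, 2L))
  ex2 <- apply_exclusions(emb, "embryo")
  expect_equal(ex2$retained$nucleus, 2:3)
  expect_equal(ex2$audit$reason, "no Huwe1 signal")
  expect_equal(nrow(ex2$retained) + nrow(ex2$audit), ex2$n_input)
})
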