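test_that("gaussian smoothing preserves constants, mean, and kernel mass", {
  const <- pixel_image(matrix(7, 32, 32), 0.1)
  expect_equal(gaussian_smooth(const, 3)$values, const$values,
               tolerance = 1e-10)
  img <- pixel_image(matrix(runif(64 * 64, 0, 100), 64, 64), 0.1)
  expect_identical(gaussian_smooth(img, 0), img)  # sigma = 0 is identity
  expect_equal(mean(gaussian_smooth(img, 2)$values), mean(img$values),
               tolerance = 1e-8)
  # unit impulse: response is the discrete Gaussian kernel, total mass 1
  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  k <- gaussian_smooth(pixel_image(imp, 0.1), 2)$values
  expect_equal(sum(k), 1, tolerance = 1e-6)
  offsets <- c(0, 1, 2, 4)
  expect_equal(k[17, 17 + offsets] / k[17, 17],
               exp(-offsets^2 / (2 * 2^2)), tolerance = 1e-3)
  expect_error(gaussian_smooth(img, -1), "non-negative")
})

test_that("otsu threshold separates a bimodal image and rejects constants", {
  v <- matrix(c(rep(10, 50), rep(100, 50)), 10, 10)
  t <- otsu_threshold(pixel_image(v, 0.1))
  expect_true(t >= 10 && t < 100)
  expect_equal(sum(v > t), 50)
  expect_error(otsu_threshold(pixel_image(matrix(5, 4, 4), 0.1)), "constant")
})

test_that("otsu agrees with the exhaustive-search oracle on random histograms", {
  set.seed(99)
  for (i in 1:100) {
    v <- switch(1 + i %% 4,
      c(rnorm(200, 20, 4), rnorm(100, 80, 10)),
      runif(300, 0, 100),
      c(rexp(200, 1 / 10), rnorm(50, 60, 5)),
      c(rnorm(150, 30, 2), rnorm(150, 35, 2)))
    v <- pmax(v, 0)
    img <- pixel_image(matrix(v, length(v), 1), 0.1)
    expect_equal(otsu_threshold(img), otsu_bruteforce(v), tolerance = 1e-9)
  }
})

test_that("adding a constant shifts the otsu threshold by that constant", {
  set.seed(7)
  v <- c(rnorm(300, 20, 5), rnorm(200, 70, 8))
  v <- pmax(v, 0)
  img <- pixel_image(matrix(v, length(v), 1), 0.1)
  t0 <- otsu_threshold(img)
  t1 <- otsu_threshold(pixel_image(matrix(v + 50, length(v), 1), 0.1))
  bin_width <- diff(range(v)) / 256
  expect_equal(t1 - 50, t0, tolerance = bin_width)
})

test_that("otsu is consistent with EBImage's implementation", {
  set.seed(13)
  v <- matrix(pmin(pmax(c(rnorm(500, 0.2, 0.05), rnorm(524, 0.7, 0.1)), 0), 1),
              32, 32)
  t_pkg <- otsu_threshold(pixel_image(v, 0.1))
  t_ebi <- EBImage::otsu(EBImage::Image(v), range = range(v), levels = 256)
  bin_width <- diff(range(v)) / 256
  expect_equal(t_pkg, t_ebi, tolerance = 2 * bin_width)
})

test_that("segmentation recovers well-separated synthetic nuclei exactly", {
  cfg <- quick_cell_config(n_nuclei = 5L, noise_sd = 0, seed = 21L)
  f <- generate_cell_field(cfg)
  lm <- segment_nuclei(f$channels$DNA)
  expect_equal(max(lm$labels), 5)
  # per-object area within 5% of the planted truth, matched by centroid
  fe <- object_features(lm)
  tr <- f$truth$nuclei
  for (i in seq_len(nrow(fe))) {
    j <- which.min((tr$centroid_row - fe$centroid_row[i])^2 +
                     (tr$centroid_col - fe$centroid_col[i])^2)
    expect_lt(abs(fe$area_um2[i] - tr$area_um2[j]) / tr$area_um2[j], 0.05)
  }
})

test_that("watershed splits two overlapping ellipses with distinct cores", {
  cfg <- quick_cell_config(n_nuclei = 4L, noise_sd = 0,
                           touching_fraction = 0.5, seed = 22L)
  f <- generate_cell_field(cfg)
  # the touching pair merges into one DNA component ...
  comp <- EBImage::bwlabel((f$channels$DNA$values > cfg$background_level) * 1)
  expect_lt(max(comp), 4)
  # ... but the watershed chain recovers all planted nuclei
  lm <- segment_nuclei(f$channels$DNA)
  expect_equal(max(lm$labels), 4)
})

test_that("blank and constant images yield empty label maps with a warning", {
  blank <- pixel_image(matrix(0, 64, 64), 0.25)
  expect_warning(lm <- segment_nuclei(blank), "constant|foreground")
  expect_equal(max(lm$labels), 0)
})

test_that("feret diameter follows the pixel-corner convention", {
  ps <- 0.5
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(feret_max(single, ps), sqrt(2) * ps)
  row10 <- matrix(FALSE, 3, 12); row10[2, 2:11] <- TRUE
  expect_equal(feret_max(row10, ps), sqrt(10^2 + 1^2) * ps)
  expect_error(feret_max(matrix(FALSE, 3, 3), ps), "empty")
})

test_that("feret equals the all-pairs boundary oracle on random blobs", {
  set.seed(31)
  n_checked <- 0
  while (n_checked < 50) {
    m <- matrix(runif(40 * 40), 40, 40)
    sm <- EBImage::gblur(m, 2)
    mask_all <- sm > quantile(sm, 0.85)
    comp <- EBImage::bwlabel(mask_all * 1)
    for (id in seq_len(max(comp))) {
      obj <- comp == id
      if (sum(obj) < 5) next
      expect_equal(feret_max(obj, 0.3), feret_bruteforce(obj, 0.3),
                   tolerance = 1e-12)
      n_checked <- n_checked + 1
    }
  }
})

test_that("circularity matches closed forms and digitization bounds", {
  # ideal disc: area pi r^2, Feret 2r -> exactly 1
  expect_equal(circularity(pi * 4^2, 2 * 4), 1.0)
  # square of side s: area s^2, Feret s sqrt(2) -> sqrt(2/pi)
  expect_equal(circularity(3^2, 3 * sqrt(2)), sqrt(2 / pi))
  # digitized disc of radius 20 px
  m <- disc_mask(c(64, 64), 32, 32, 20)
  area <- sum(m) * 0.25^2
  circ <- circularity(area, feret_max(m, 0.25))
  expect_gte(circ, 0.95); expect_lte(circ, 1.05)
  expect_error(circularity(-1, 2), "positive")
})

test_that("segmented object circularity never exceeds the isodiametric bound", {
  cfg <- quick_cell_config(n_nuclei = 8L, seed = 23L,
                           nucleus_eccentricity_range = c(0, 0.8))
  f <- generate_cell_field(cfg)
  fe <- object_features(segment_nuclei(f$channels$DNA))
  expect_true(all(fe$circularity <= 1.1))
})

test_that("shape filters use closed intervals and the stated defaults", {
  feats <- data.frame(label = 1:3, area_um2 = c(80, 200, 500),
                      feret_max_um = 1, circularity = 0.9,
                      centroid_row = 0, centroid_col = 0)
  emb <- filter_ranges("embryo")
  expect_equal(filter_objects(feats, emb$area, emb$circ), 2L)
  expect_equal(emb$area, c(100, 450)); expect_equal(emb$circ, c(0.7, 1))
  cell <- filter_ranges("cell")
  expect_equal(cell$area, c(50, 300)); expect_equal(cell$circ, c(0.5, 1))
  # boundary value retained (closed interval)
  feats$area_um2[1] <- 100
  expect_equal(filter_objects(feats, emb$area, emb$circ), c(1L, 2L))
  expect_equal(filter_objects(feats[0, ], emb$area, emb$circ), integer(0))
})
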