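# Independent oracles and fixture builders shared across tests.

# Digitized disc mask: pixels whose centre lies within radius r of the
# centre (row0, col0).
disc_mask <- function(shape, row0, col0, r) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (rr - row0)^2 + (cc - col0)^2 <= r^2
}

# Brute-force maximal Feret diameter: all pairwise distances between the
# pixel corners of the object's boundary pixels (a pixel is boundary if
# any 4-neighbour is outside the mask).
feret_bruteforce <- function(mask, pixel_size) {
  px <- which(mask != 0, arr.ind = TRUE)
  inside <- function(r, c) r >= 1 & r <= nrow(mask) & c >= 1 & c <= ncol(mask) &
    mask[cbind(pmin(pmax(r, 1), nrow(mask)), pmin(pmax(c, 1), ncol(mask)))] != 0
  nb <- inside(px[, 1] - 1, px[, 2]) & inside(px[, 1] + 1, px[, 2]) &
    inside(px[, 1], px[, 2] - 1) & inside(px[, 1], px[, 2] + 1)
  bd <- px[!nb, , drop = FALSE]
  corners <- rbind(cbind(bd[, 1] - 0.5, bd[, 2] - 0.5),
                   cbind(bd[, 1] - 0.5, bd[, 2] + 0.5),
                   cbind(bd[, 1] + 0.5, bd[, 2] - 0.5),
                   cbind(bd[, 1] + 0.5, bd[, 2] + 0.5))
  sqrt(max(dist(corners)^2)) * pixel_size
}

# Exhaustive-search Otsu threshold: explicit loop over all 256-bin cut
# points, recomputing class weights and means from the histogram.
otsu_bruteforce <- function(values, levels = 256L) {
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  bin <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  h <- as.numeric(tabulate(bin, nbins = levels))
  centers <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  best_bcv <- -Inf
  best_edges <- numeric(0)
  for (k in 1:(levels - 1L)) {
    w0 <- sum(h[1:k]); w1 <- sum(h[(k + 1):levels])
    if (w0 == 0 || w1 == 0) bcv <- -Inf
    else {
      mu0 <- sum(h[1:k] * centers[1:k]) / w0
      mu1 <- sum(h[(k + 1):levels] * centers[(k + 1):levels]) / w1
      bcv <- w0 * w1 * (mu0 - mu1)^2
    }
    if (bcv > best_bcv) {
      best_bcv <- bcv; best_edges <- breaks[k + 1L]
    } else if (bcv == best_bcv && is.finite(bcv)) {
      best_edges <- c(best_edges, breaks[k + 1L])
    }
  }
  mean(best_edges)
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(n1 + n2, n1) group assignments (no ties assumed).
wilcoxon_enum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  u_all <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Small, quick synthetic cell config used by several tests; coarse pixel
# grid keeps nuclei a few tens of pixels across.
quick_cell_config <- function(n_nuclei = 10L, min_centroid_spacing = 24,
                              nucleus_area_range = c(80, 250),
                              image_shape = c(512L, 512L), ...) {
  synth_field_config(mode = "cell", image_shape = image_shape,
                     pixel_size = 0.25, n_nuclei = n_nuclei,
                     min_centroid_spacing = min_centroid_spacing,
                     nucleus_area_range = nucleus_area_range, ...)
}

quick_embryo_config <- function(...) {
  synth_field_config(mode = "embryo", image_shape = c(448L, 448L),
                     pixel_size = 0.25, nucleus_area_range = c(150, 350),
                     min_centroid_spacing = 24,
                     cloud_count_probs = c(0.1, 0.8, 0.1, 0), ...)
}

ring_width_px_for <- function(pixel_size) round(2.64 / pixel_size)
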