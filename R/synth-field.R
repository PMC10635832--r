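# Seeded synthetic microscopy fields with full ground truth.
# Nuclei are uniform-intensity ellipses over a cytoplasmic halo; Xist
# clouds and Huwe1 nascent-transcript foci are sum-normalised Gaussian
# blobs, so planted integrated intensities are conserved exactly up to
# window truncation at 4 sigma.

run_seeded <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Configuration of a synthetic microscopy field
#'
#' Describes the statistical structure of one simulated field of view:
#' elliptical nuclei over a cytoplasmic halo, a translocation (GATA6-HA)
#' channel with a configurable true nuclear:cytoplasmic intensity ratio,
#' per-nucleus Xist RNA clouds with configurable integrated intensity and
#' a condition-dependent intensity scale, and Huwe1 nascent-transcript
#' foci encoding embryo sex.
#'
#' @param mode `"cell"` or `"embryo"`; selects the default pixel size
#'   (0.088 um/px widefield cell imaging, 0.07 um/px confocal embryo
#'   imaging), nucleus size range and spacing.
#' @param image_shape Height and width in pixels.
#' @param pixel_size um per pixel (> 0).
#' @param n_nuclei Number of nuclei to place.
#' @param nucleus_area_range Closed range of true nucleus areas, um^2.
#' @param nucleus_eccentricity_range Closed range of ellipse
#'   eccentricities in `[0, 1)`.
#' @param min_centroid_spacing Minimum distance between nucleus
#'   centroids, um.
#' @param touching_fraction Fraction of nuclei placed as close pairs
#'   (centroid distance below the spacing) to exercise watershed
#'   splitting; 0 disables.
#' @param cytoplasm_halo_width Width of the cytoplasmic halo rendered
#'   around each nucleus, um.
#' @param gata_cyt_mean Mean GATA6-HA intensity in the halo.
#' @param nuc_cyt_ratio_true True nuclear:cytoplasmic intensity ratio of
#'   the GATA6-HA channel (>= 0).
#' @param ratio_by_cloud_count Optional numeric vector of length 4 giving
#'   the true nuc:cyt ratio for nuclei with 0, 1, 2 and 3 clouds;
#'   overrides `nuc_cyt_ratio_true` and couples translocation to Xist
#'   state for dose-response simulations.
#' @param cloud_count_probs Probability vector over 0-3 Xist clouds per
#'   nucleus; must sum to 1.
#' @param cloud_integrated_intensity Integrated (summed) intensity
#'   planted per cloud, before condition scaling.
#' @param cloud_sigma Gaussian radius of a cloud, um.
#' @param condition_scale Multiplier on cloud intensity encoding the
#'   experimental condition (1 = control; e.g. 0.2 for a knock-out with
#'   5-fold reduced Xist).
#' @param huwe1_spots_per_nucleus 1 or 2 nascent-transcript foci
#'   (male / female); used by [generate_embryo_field()].
#' @param huwe1_spot_intensity Integrated intensity per Huwe1 focus.
#' @param huwe1_spot_sigma Gaussian radius of a focus, um.
#' @param dna_nuc_mean DNA-stain intensity inside nuclei.
#' @param background_level Additive background on every channel.
#' @param noise_sd Additive Gaussian noise sd on every channel.
#' @param condition_label Free-text condition label stored in the ground
#'   truth.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   fields.
#' @return A list of class `synth_field_config`.
#' @export
synth_field_config <- function(mode = c("cell", "embryo"),
                               image_shape = c(512L, 512L),
                               pixel_size = NULL,
                               n_nuclei = 8L,
                               nucleus_area_range = NULL,
                               nucleus_eccentricity_range = c(0, 0.6),
                               min_centroid_spacing = NULL,
                               touching_fraction = 0,
                               cytoplasm_halo_width = 3,
                               gata_cyt_mean = 100,
                               nuc_cyt_ratio_true = 1.5,
                               ratio_by_cloud_count = NULL,
                               cloud_count_probs = c(0.4, 0.45, 0.15, 0),
                               cloud_integrated_intensity = 2e4,
                               cloud_sigma = 0.5,
                               condition_scale = 1,
                               huwe1_spots_per_nucleus = 2L,
                               huwe1_spot_intensity = 4e3,
                               huwe1_spot_sigma = 0.25,
                               dna_nuc_mean = 150,
                               background_level = 10,
                               noise_sd = 2,
                               condition_label = "control",
                               seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(pixel_size))
    pixel_size <- if (mode == "cell") 0.088 else 0.07
  if (is.null(nucleus_area_range))
    nucleus_area_range <- if (mode == "cell") c(80, 250) else c(150, 400)
  if (is.null(min_centroid_spacing))
    min_centroid_spacing <- if (mode == "cell") 24 else 26
  cfg <- list(mode = mode,
              image_shape = as.integer(image_shape),
              pixel_size = pixel_size,
              n_nuclei = as.integer(n_nuclei),
              nucleus_area_range = nucleus_area_range,
              nucleus_eccentricity_range = nucleus_eccentricity_range,
              min_centroid_spacing = min_centroid_spacing,
              touching_fraction = touching_fraction,
              cytoplasm_halo_width = cytoplasm_halo_width,
              gata_cyt_mean = gata_cyt_mean,
              nuc_cyt_ratio_true = nuc_cyt_ratio_true,
              ratio_by_cloud_count = ratio_by_cloud_count,
              cloud_count_probs = cloud_count_probs,
              cloud_integrated_intensity = cloud_integrated_intensity,
              cloud_sigma = cloud_sigma,
              condition_scale = condition_scale,
              huwe1_spots_per_nucleus = as.integer(huwe1_spots_per_nucleus),
              huwe1_spot_intensity = huwe1_spot_intensity,
              huwe1_spot_sigma = huwe1_spot_sigma,
              dna_nuc_mean = dna_nuc_mean,
              background_level = background_level,
              noise_sd = noise_sd,
              condition_label = condition_label,
              seed = as.integer(seed))
  validate_synth_field_config(cfg)
  structure(cfg, class = "synth_field_config")
}

validate_synth_field_config <- function(cfg) {
  stopifnot(length(cfg$image_shape) == 2L, all(cfg$image_shape >= 16L),
            cfg$pixel_size > 0, cfg$n_nuclei >= 1L)
  if (cfg$nucleus_area_range[1] > cfg$nucleus_area_range[2] ||
      any(cfg$nucleus_area_range <= 0))
    stop("invalid nucleus_area_range")
  e <- cfg$nucleus_eccentricity_range
  if (e[1] > e[2] || e[1] < 0 || e[2] >= 1)
    stop("nucleus_eccentricity_range must lie in [0, 1) with low <= high")
  p <- cfg$cloud_count_probs
  if (length(p) != 4L || any(p < 0) || any(p > 1) ||
      abs(sum(p) - 1) > 1e-8)
    stop("cloud_count_probs must be 4 probabilities over {0,1,2,3} summing to 1")
  if (!is.null(cfg$ratio_by_cloud_count) &&
      (length(cfg$ratio_by_cloud_count) != 4L ||
       any(cfg$ratio_by_cloud_count < 0)))
    stop("ratio_by_cloud_count must be 4 non-negative values")
  stopifnot(cfg$nuc_cyt_ratio_true >= 0, cfg$condition_scale >= 0,
            cfg$cloud_sigma > 0, cfg$huwe1_spots_per_nucleus %in% 1:2,
            cfg$background_level >= 0, cfg$noise_sd >= 0,
            cfg$touching_fraction >= 0, cfg$touching_fraction <= 1)
  invisible(cfg)
}

# Ellipse pixel mask as arr.ind rows within the image; scale enlarges
# both semi-axes additively (pixels).
ellipse_pixels <- function(shape, center, a, b, theta, grow = 0) {
  a <- a + grow; b <- b + grow
  r0 <- max(1L, floor(center[1] - max(a, b)))
  r1 <- min(shape[1], ceiling(center[1] + max(a, b)))
  c0 <- max(1L, floor(center[2] - max(a, b)))
  c1 <- min(shape[2], ceiling(center[2] + max(a, b)))
  rr <- r0:r1; cc <- c0:c1
  dx <- outer(rr - center[1], rep(1, length(cc)))
  dy <- outer(rep(1, length(rr)), cc - center[2])
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- which(u^2 + v^2 <= 1, arr.ind = TRUE)
  cbind(row = rr[inside[, 1]], col = cc[inside[, 2]])
}

# Add a sum-normalised Gaussian blob of given integrated intensity.
add_gaussian_blob <- function(mat, center, sigma_px, intensity) {
  w <- ceiling(4 * sigma_px)
  r0 <- max(1L, floor(center[1]) - w); r1 <- min(nrow(mat), floor(center[1]) + w)
  c0 <- max(1L, floor(center[2]) - w); c1 <- min(ncol(mat), floor(center[2]) + w)
  rr <- r0:r1; cc <- c0:c1
  kr <- exp(-(rr - center[1])^2 / (2 * sigma_px^2))
  kc <- exp(-(cc - center[2])^2 / (2 * sigma_px^2))
  k <- outer(kr, kc)
  mat[rr, cc] <- mat[rr, cc] + intensity * k / sum(k)
  mat
}

place_nuclei <- function(cfg) {
  shape <- cfg$image_shape
  ps <- cfg$pixel_size
  n <- cfg$n_nuclei
  halo_px <- cfg$cytoplasm_halo_width / ps
  spacing_px <- cfg$min_centroid_spacing / ps
  area <- runif(n, cfg$nucleus_area_range[1], cfg$nucleus_area_range[2])
  ecc <- runif(n, cfg$nucleus_eccentricity_range[1],
               cfg$nucleus_eccentricity_range[2])
  theta <- runif(n, 0, pi)
  q <- sqrt(1 - ecc^2)
  a_um <- sqrt(area / (pi * q))
  a_px <- a_um / ps
  b_px <- a_px * q
  margin <- a_px + halo_px + 2
  if (any(2 * margin >= pmin(shape[1], shape[2])))
    stop(errorCondition(
      "image too small for configured nucleus size and halo",
      class = c("xq_placement_error", "error", "condition"), placed = 0L))
  n_pairs <- floor(cfg$touching_fraction * n / 2)
  partner_of <- rep(NA_integer_, n)
  if (n_pairs > 0)
    for (i in seq_len(n_pairs)) partner_of[2 * i] <- 2L * i - 1L
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(2000L)) {
      if (!is.na(partner_of[i])) {
        j <- partner_of[i]
        d <- 0.8 * (sqrt(a_px[i] * b_px[i]) + sqrt(a_px[j] * b_px[j]))
        ang <- runif(1, 0, 2 * pi)
        cand <- centers[j, ] + d * c(cos(ang), sin(ang))
      } else {
        cand <- c(runif(1, margin[i], shape[1] - margin[i]),
                  runif(1, margin[i], shape[2] - margin[i]))
      }
      if (cand[1] < margin[i] || cand[1] > shape[1] - margin[i] ||
          cand[2] < margin[i] || cand[2] > shape[2] - margin[i]) next
      ok <- TRUE
      for (j in seq_len(i - 1L)) {
        dd <- sqrt(sum((cand - centers[j, ])^2))
        lim <- if (!is.na(partner_of[i]) && partner_of[i] == j) 0 else spacing_px
        if (dd < lim) { ok <- FALSE; break }
      }
      if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed)
      stop(errorCondition(
        sprintf("could not place nucleus %d of %d without violating min_centroid_spacing (placed %d)",
                i, n, i - 1L),
        class = c("xq_placement_error", "error", "condition"),
        placed = i - 1L))
  }
  data.frame(nucleus = seq_len(n), centroid_row = centers[, 1],
             centroid_col = centers[, 2], area_um2 = area,
             a_px = a_px, b_px = b_px, theta = theta)
}

render_field <- function(cfg, sex = NA_character_,
                         channels = c("DNA", "GATA6", "Xist")) {
  shape <- cfg$image_shape
  ps <- cfg$pixel_size
  halo_px <- cfg$cytoplasm_halo_width / ps
  nuc <- place_nuclei(cfg)
  n <- nrow(nuc)
  masks <- lapply(seq_len(n), function(i)
    ellipse_pixels(shape, c(nuc$centroid_row[i], nuc$centroid_col[i]),
                   nuc$a_px[i], nuc$b_px[i], nuc$theta[i]))

  # planted per-nucleus states; inverse-CDF sampling consumes exactly one
  # uniform per nucleus, so other channels are invariant to cloud settings
  counts <- findInterval(runif(n), cumsum(cfg$cloud_count_probs)[1:3])
  ratio <- if (!is.null(cfg$ratio_by_cloud_count))
    cfg$ratio_by_cloud_count[counts + 1L] else rep(cfg$nuc_cyt_ratio_true, n)
  huwe1 <- if ("Huwe1" %in% channels) {
    if (!is.na(sex)) (if (sex == "female") 2L else 1L)
    else cfg$huwe1_spots_per_nucleus
  } else NA_integer_
  huwe1 <- rep(huwe1, n)

  # noise drawn before any position sampling, in fixed channel order, so
  # the DNA/GATA6 channels do not depend on cloud or spot placement
  noise <- if (cfg$noise_sd > 0)
    lapply(stats::setNames(channels, channels), function(nm)
      matrix(rnorm(prod(shape), 0, cfg$noise_sd), shape[1], shape[2]))
  else NULL

  ch <- list()
  bg <- cfg$background_level
  if ("DNA" %in% channels) {
    m <- matrix(bg, shape[1], shape[2])
    for (i in seq_len(n)) m[masks[[i]]] <- cfg$dna_nuc_mean
    ch$DNA <- m
  }
  if ("GATA6" %in% channels) {
    m <- matrix(bg, shape[1], shape[2])
    for (i in seq_len(n)) {
      halo <- ellipse_pixels(shape, c(nuc$centroid_row[i], nuc$centroid_col[i]),
                             nuc$a_px[i], nuc$b_px[i], nuc$theta[i],
                             grow = halo_px)
      m[halo] <- cfg$gata_cyt_mean
    }
    for (i in seq_len(n)) m[masks[[i]]] <- ratio[i] * cfg$gata_cyt_mean
    ch$GATA6 <- m
  }

  clouds <- data.frame(nucleus = integer(0), row = numeric(0),
                       col = numeric(0), sigma_px = numeric(0),
                       intensity = numeric(0))
  if ("Xist" %in% channels) {
    m <- matrix(bg, shape[1], shape[2])
    sig_px <- cfg$cloud_sigma / ps
    for (i in seq_len(n)) {
      if (counts[i] == 0) next
      # clouds are distinct Xist territories: keep them far enough apart
      # that thresholding never fuses neighbouring blobs
      pts <- sample_points_in_ellipse(
        counts[i], c(nuc$centroid_row[i], nuc$centroid_col[i]),
        0.6 * nuc$a_px[i], 0.6 * nuc$b_px[i], nuc$theta[i],
        min_sep = 10 * sig_px)
      for (k in seq_len(nrow(pts))) {
        inten <- cfg$cloud_integrated_intensity * cfg$condition_scale
        m <- add_gaussian_blob(m, pts[k, ], sig_px, inten)
        clouds <- rbind(clouds, data.frame(
          nucleus = i, row = pts[k, 1], col = pts[k, 2],
          sigma_px = sig_px, intensity = inten))
      }
    }
    ch$Xist <- m
  }
  if ("Huwe1" %in% channels) {
    m <- matrix(bg, shape[1], shape[2])
    sig_px <- cfg$huwe1_spot_sigma / ps
    for (i in seq_len(n)) {
      pts <- sample_points_in_ellipse(
        huwe1[i], c(nuc$centroid_row[i], nuc$centroid_col[i]),
        0.45 * nuc$a_px[i], 0.45 * nuc$b_px[i], nuc$theta[i],
        min_sep = max(6 * sig_px, 0.4 * nuc$b_px[i]))
      for (k in seq_len(nrow(pts)))
        m <- add_gaussian_blob(m, pts[k, ], sig_px, cfg$huwe1_spot_intensity)
    }
    ch$Huwe1 <- m
  }

  if (!is.null(noise))
    ch <- mapply(function(m, nz) pmax(m + nz, 0), ch, noise[names(ch)],
                 SIMPLIFY = FALSE)

  nuc$true_nuc_cyt_ratio <- ratio
  nuc$true_cloud_count <- counts
  nuc$true_huwe1_count <- huwe1
  truth <- structure(list(
    nuclei = nuc, clouds = clouds,
    condition = cfg$condition_label, sex = sex,
    seed = cfg$seed, pixel_size = ps), class = "ground_truth")
  structure(list(
    channels = lapply(ch, pixel_image, pixel_size = ps),
    truth = truth, config = cfg), class = "synthetic_field")
}

sample_points_in_ellipse <- function(k, center, a, b, theta, min_sep = 0) {
  pts <- matrix(NA_real_, k, 2)
  for (i in seq_len(k)) {
    for (try in seq_len(200L)) {
      r <- sqrt(runif(1)); ang <- runif(1, 0, 2 * pi)
      u <- r * cos(ang) * a; v <- r * sin(ang) * b
      cand <- center + c(u * cos(theta) - v * sin(theta),
                         u * sin(theta) + v * cos(theta))
      if (i == 1L ||
          all(sqrt(rowSums((pts[seq_len(i - 1L), , drop = FALSE] -
                            matrix(cand, i - 1L, 2, byrow = TRUE))^2)) >=
              min_sep) || try == 200L) {
        pts[i, ] <- cand; break
      }
    }
  }
  pts
}

#' Generate a synthetic cell-culture field
#'
#' Renders one field of cultured cells with three channels (DNA, GATA6-HA
#' immunofluorescence, Xist RNA-FISH) and returns the image together with
#' the full ground truth of every planted nucleus, ratio and cloud. By
#' construction the GATA6 channel mean inside each nucleus equals the
#' planted nuc:cyt ratio times the halo mean before noise, and each
#' cloud's rendered intensity sums to its planted integrated intensity
#' (up to 4-sigma window truncation).
#'
#' @param config A [synth_field_config()].
#' @return A list of class `synthetic_field` with elements `channels`
#'   (named list of [pixel_image]: DNA, GATA6, Xist), `truth` (class
#'   `ground_truth`: per-nucleus table, per-cloud table, labels, seed)
#'   and `config`.
#' @export
generate_cell_field <- function(config) {
  validate_synth_field_config(config)
  run_seeded(config$seed,
             render_field(config, channels = c("DNA", "GATA6", "Xist")))
}

#' Generate a synthetic eight-cell embryo field
#'
#' Renders an embryo with 8 nuclei and channels DNA, Xist and Huwe1. The
#' Huwe1 channel carries 2 nascent-transcript foci per nucleus for a
#' female embryo and 1 for a male; the Xist channel is scaled by the
#' configured `condition_scale`.
#'
#' @param config A [synth_field_config()] (typically `mode = "embryo"`);
#'   `n_nuclei` is forced to 8.
#' @param sex `"female"` or `"male"`.
#' @return A `synthetic_field` (see [generate_cell_field()]) whose truth
#'   records the sex label.
#' @export
generate_embryo_field <- function(config, sex = c("female", "male")) {
  sex <- match.arg(sex)
  validate_synth_field_config(config)
  config$n_nuclei <- 8L
  run_seeded(config$seed,
             render_field(config, sex = sex,
                          channels = c("DNA", "Xist", "Huwe1")))
}

#' Suggested fixed detection threshold for planted blobs
#'
#' Detection uses a fixed intensity threshold on the smoothed,
#' background-subtracted image. For a planted Gaussian blob of integrated
#' intensity I and radius sigma the peak amplitude is
#' `I / (2 * pi * sigma_px^2)`; a threshold at a small fraction of the
#' peak captures `1 - threshold/peak` of the blob's mass (exact for a 2D
#' Gaussian), so the default fraction 0.03 keeps ~97% of the planted
#' intensity inside the detected mask while staying far above the
#' smoothed noise floor.
#'
#' @param config A [synth_field_config()].
#' @param what `"cloud"` (Xist) or `"spot"` (Huwe1).
#' @param scale Condition scale the threshold must still detect; defaults
#'   to the config's `condition_scale`. When analysing several conditions
#'   with one threshold, pass the smallest scale.
#' @param fraction Threshold as a fraction of the dimmest expected peak.
#' @return Threshold in background-subtracted intensity units.
#' @export
suggest_threshold <- function(config, what = c("cloud", "spot"),
                              scale = NULL, fraction = NULL) {
  what <- match.arg(what)
  if (what == "cloud") {
    if (is.null(scale)) scale <- config$condition_scale
    if (is.null(fraction)) fraction <- 0.03
    sig_px <- config$cloud_sigma / config$pixel_size
    peak <- config$cloud_integrated_intensity * scale / (2 * pi * sig_px^2)
  } else {
    if (is.null(fraction)) fraction <- 0.1
    sig_px <- config$huwe1_spot_sigma / config$pixel_size
    peak <- config$huwe1_spot_intensity / (2 * pi * sig_px^2)
  }
  fraction * peak
}
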