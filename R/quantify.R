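# Per-nucleus measurement: ring-based nuc:cyt ratio, Xist cloud
# detection and summed intensity, Huwe1 counting, inclusion rules.

# Distance of every pixel to the boundary of each nucleus, and the
# nearest-nucleus ownership map used to resolve contested ring pixels.
ring_ownership <- function(labels, width_px) {
  lab <- labels$labels
  ids <- sort(unique(lab[lab > 0L]))
  best <- matrix(Inf, nrow(lab), ncol(lab))
  owner <- matrix(0L, nrow(lab), ncol(lab))
  dists <- list()
  for (id in ids) {
    d <- as.matrix(EBImage::imageData(EBImage::distmap((lab != id) * 1)))
    dists[[as.character(id)]] <- d
    upd <- d < best
    best[upd] <- d[upd]
    owner[upd] <- id
  }
  list(ids = ids, dists = dists, owner = owner)
}

#' Cytoplasmic ring around a nucleus
#'
#' The peri-nuclear ring used as a surrogate for the cytoplasm: all
#' pixels within `width_px` of the nucleus, excluding the nucleus itself
#' and every other nucleus. Pixels also within reach of another nucleus's
#' ring (contested pixels) are assigned to the nucleus with the nearer
#' boundary, which shrinks the ring between close neighbours. The default
#' width of 30 px corresponds to 2.64 um at 0.088 um/px.
#'
#' @param labels A [label_map] of nuclei.
#' @param nucleus Label of the nucleus of interest.
#' @param width_px Ring width in pixels.
#' @param ownership Optional precomputed [ring_ownership] (internal use,
#'   avoids recomputing distance maps per nucleus).
#' @return Logical matrix marking the ring pixels, with attribute `n_px`.
#'   An empty ring raises an error of class `xq_empty_ring`.
#' @export
cytoplasm_ring <- function(labels, nucleus, width_px = 30,
                           ownership = NULL) {
  stopifnot(inherits(labels, "label_map"), width_px >= 1)
  lab <- labels$labels
  if (!any(lab == nucleus)) stop("nucleus not present in label map")
  if (is.null(ownership)) ownership <- ring_ownership(labels, width_px)
  d <- ownership$dists[[as.character(nucleus)]]
  ring <- d > 0 & d <= width_px & lab == 0L & ownership$owner == nucleus
  if (!any(ring))
    stop(errorCondition(
      sprintf("empty cytoplasmic ring for nucleus %d", nucleus),
      class = c("xq_empty_ring", "error", "condition")))
  attr(ring, "n_px") <- sum(ring)
  ring
}

#' Nuclear-to-cytoplasmic intensity ratio
#'
#' Mean intensity over the nucleus mask divided by mean intensity over
#' the cytoplasmic ring mask; a proxy for nuclear translocation of a
#' tagged transcription factor.
#'
#' @param channel A [pixel_image] (e.g. the GATA6-HA channel).
#' @param nucleus_mask,ring_mask Non-empty logical masks.
#' @return The ratio; `NA` (with a warning) if the ring mean is zero.
#' @export
nuc_cyt_ratio <- function(channel, nucleus_mask, ring_mask) {
  stopifnot(inherits(channel, "pixel_image"))
  if (!any(nucleus_mask)) stop("empty nucleus mask")
  if (!any(ring_mask)) stop("empty ring mask")
  cyt <- mean(channel$values[ring_mask])
  if (cyt == 0) {
    warning("zero cytoplasmic mean; ratio undefined")
    return(NA_real_)
  }
  mean(channel$values[nucleus_mask]) / cyt
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background as the grayscale morphological opening
#' of the image with a disc of the given radius (the background an
#' idealised ball of that radius can reach from below) and subtracts it.
#' Structures narrower than the ball, such as RNA-FISH spots, survive;
#' the output is non-negative everywhere.
#'
#' @param img A [pixel_image].
#' @param radius_px Ball radius in pixels (> 0, smaller than the image).
#' @return Background-subtracted [pixel_image].
#' @export
rolling_ball <- function(img, radius_px = 20) {
  stopifnot(inherits(img, "pixel_image"))
  if (!is.numeric(radius_px) || radius_px <= 0)
    stop("'radius_px' must be positive")
  size <- 2L * as.integer(radius_px) + 1L
  if (size > min(dim(img$values)))
    stop("rolling_ball: radius larger than the image")
  v <- img$values
  mx <- max(v)
  if (mx == 0) return(img)
  # EBImage grayscale morphology operates on [0,1]; flat structuring
  # elements commute with positive scaling, so normalising is exact
  brush <- EBImage::makeBrush(size, shape = "disc")
  bg <- as.matrix(EBImage::opening(v / mx, brush)) * mx
  pixel_image(pmax(v - bg, 0), img$pixel_size)
}

#' Parameters of the spot/cloud detection chain
#'
#' @param threshold Fixed intensity threshold applied to the smoothed,
#'   background-subtracted image (required; units of that image). See
#'   [suggest_threshold()] for a principled choice on synthetic data.
#' @param smooth_sigma Gaussian smoothing sd in pixels before background
#'   subtraction.
#' @param ball_radius Rolling-ball radius in pixels.
#' @param min_area_px Minimum component area in pixels (clouds default 5;
#'   use 2 for point-like nascent-transcript foci).
#' @param circ_range Closed circularity interval applied to components,
#'   or `NULL` for none (cell-mode cloud detection uses `c(0.5, 1)`;
#'   embryo mode applies no circularity filter).
#' @param intensity_on `"bgsub"` sums cloud intensity on the unsmoothed
#'   background-subtracted channel (default); `"raw"` on the raw channel.
#' @return A list of class `cloud_params`.
#' @export
cloud_params <- function(threshold, smooth_sigma = 1, ball_radius = 20,
                         min_area_px = 5, circ_range = c(0.5, 1),
                         intensity_on = c("bgsub", "raw")) {
  stopifnot(is.numeric(threshold), threshold >= 0, smooth_sigma >= 0,
            ball_radius > 0, min_area_px >= 1)
  if (!is.null(circ_range))
    stopifnot(length(circ_range) == 2L, circ_range[1] <= circ_range[2])
  structure(list(threshold = threshold, smooth_sigma = smooth_sigma,
                 ball_radius = ball_radius, min_area_px = min_area_px,
                 circ_range = circ_range,
                 intensity_on = match.arg(intensity_on)),
            class = "cloud_params")
}

# Shared detection chain: smooth -> rolling ball -> fixed threshold ->
# connected components. Returns component label matrix plus the images.
detect_components <- function(channel, params) {
  sm <- gaussian_smooth(channel, params$smooth_sigma)
  det <- rolling_ball(sm, params$ball_radius)
  mask <- det$values > params$threshold
  comp <- EBImage::bwlabel(mask * 1)
  list(comp = as.matrix(EBImage::imageData(comp)), det = det)
}

#' Detect RNA-FISH clouds within nuclei
#'
#' Smooths the FISH channel, subtracts the rolling-ball background,
#' applies the fixed intensity threshold, labels connected components,
#' optionally filters them by circularity (cell mode), and assigns each
#' component to the nucleus containing its intensity-weighted centroid.
#' Components outside all nuclei are discarded.
#'
#' @param channel A [pixel_image] (Xist RNA-FISH channel).
#' @param labels A [label_map] of nuclei.
#' @param params A [cloud_params()].
#' @return Data frame with one row per retained cloud: `cloud`,
#'   `nucleus`, `area_um2`, `circularity`, `summed_intensity`,
#'   `centroid_row`, `centroid_col`. Zero rows when nothing exceeds the
#'   threshold.
#' @export
detect_clouds <- function(channel, labels, params) {
  stopifnot(inherits(channel, "pixel_image"), inherits(labels, "label_map"),
            inherits(params, "cloud_params"))
  dc <- detect_components(channel, params)
  comp <- dc$comp
  inten <- if (params$intensity_on == "bgsub")
    rolling_ball(channel, params$ball_radius)$values else channel$values
  ps <- channel$pixel_size
  out <- list()
  ids <- sort(unique(comp[comp > 0L]))
  k <- 0L
  for (id in ids) {
    m <- comp == id
    px <- which(m, arr.ind = TRUE)
    if (nrow(px) < params$min_area_px) next
    area <- nrow(px) * ps^2
    fer <- feret_max(m, ps)
    circ <- circularity(area, fer)
    if (!is.null(params$circ_range) &&
        (circ < params$circ_range[1] || circ > params$circ_range[2])) next
    w <- dc$det$values[px]
    cr <- sum(px[, 1] * w) / sum(w)
    cc <- sum(px[, 2] * w) / sum(w)
    nuc <- labels$labels[round(cr), round(cc)]
    if (nuc == 0L) next
    k <- k + 1L
    out[[k]] <- data.frame(cloud = k, nucleus = as.integer(nuc),
                           area_um2 = area, circularity = circ,
                           summed_intensity = sum(inten[px]),
                           centroid_row = cr, centroid_col = cc)
  }
  if (k == 0L)
    return(data.frame(cloud = integer(0), nucleus = integer(0),
                      area_um2 = numeric(0), circularity = numeric(0),
                      summed_intensity = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0)))
  do.call(rbind, out)
}

#' Summed intensity within a mask
#'
#' Sum of (background-subtracted) channel values over a detected cloud
#' mask — the per-cloud quantity compared between conditions.
#'
#' @param channel_bgsub A [pixel_image], typically the output of
#'   [rolling_ball()].
#' @param mask Non-empty logical matrix.
#' @return The summed intensity.
#' @export
summed_intensity <- function(channel_bgsub, mask) {
  stopifnot(inherits(channel_bgsub, "pixel_image"))
  if (!any(mask)) stop("summed_intensity: empty mask")
  sum(channel_bgsub$values[mask])
}

#' Count Huwe1 nascent-transcript foci in one nucleus
#'
#' Runs the same detection chain as [detect_clouds()] (with a smaller
#' minimum area, default 2 px, and no circularity filter) and counts the
#' components whose intensity-weighted centroid falls inside the given
#' nucleus mask.
#'
#' @param channel A [pixel_image] (Huwe1 RNA-FISH channel).
#' @param nucleus_mask Logical matrix for one nucleus.
#' @param params A [cloud_params()]; defaults come from
#'   [huwe1_params()] conventions when built by the caller.
#' @return Integer count of foci.
#' @export
count_huwe1 <- function(channel, nucleus_mask, params) {
  counts <- huwe1_counts(channel,
                         label_map(nucleus_mask * 1L, channel$pixel_size),
                         params)
  if (nrow(counts) == 0L) 0L else counts$huwe1_count[1]
}

#' Count Huwe1 foci for every nucleus of a label map
#'
#' @param channel A [pixel_image] (Huwe1 channel).
#' @param labels A [label_map] of nuclei.
#' @param params A [cloud_params()] (use `min_area_px = 2`,
#'   `circ_range = NULL` for point-like foci).
#' @return Data frame `nucleus`, `huwe1_count` (one row per label,
#'   including zero counts).
#' @export
huwe1_counts <- function(channel, labels, params) {
  stopifnot(inherits(channel, "pixel_image"), inherits(labels, "label_map"),
            inherits(params, "cloud_params"))
  dc <- detect_components(channel, params)
  comp <- dc$comp
  ids <- sort(unique(comp[comp > 0L]))
  nuc_ids <- sort(unique(labels$labels[labels$labels > 0L]))
  counts <- stats::setNames(rep(0L, length(nuc_ids)), nuc_ids)
  for (id in ids) {
    px <- which(comp == id, arr.ind = TRUE)
    if (nrow(px) < params$min_area_px) next
    w <- dc$det$values[px]
    cr <- round(sum(px[, 1] * w) / sum(w))
    cc <- round(sum(px[, 2] * w) / sum(w))
    nuc <- labels$labels[cr, cc]
    if (nuc > 0L)
      counts[as.character(nuc)] <- counts[as.character(nuc)] + 1L
  }
  data.frame(nucleus = as.integer(names(counts)),
             huwe1_count = as.integer(counts), row.names = NULL)
}

#' Call embryo sex from per-nucleus Huwe1 counts
#'
#' Huwe1 is X-linked and not yet silenced at the stages analysed, so a
#' female (XX) nucleus shows two nascent-transcript signals and a male
#' (XY) nucleus one. The call is `"female"` if the median per-nucleus
#' count equals 2, `"male"` if it equals 1, otherwise `"ambiguous"`.
#'
#' @param counts Integer vector of per-nucleus Huwe1 counts (>= 1 value).
#' @return `"female"`, `"male"` or `"ambiguous"`.
#' @export
embryo_sex <- function(counts) {
  if (length(counts) == 0L) stop("embryo_sex: no nuclei")
  med <- stats::median(counts)
  if (med == 2) "female" else if (med == 1) "male" else "ambiguous"
}

#' Apply the per-cell inclusion rules
#'
#' Cell mode excludes cells with more than two detected Xist objects
#' (segmentation errors); embryo mode excludes nuclei without a Huwe1
#' signal. Every dropped record is logged with its reason, so that
#' retained + excluded always reconciles with the input.
#'
#' @param records Data frame of per-cell records; cell mode requires a
#'   `n_xist_clouds` column, embryo mode a `huwe1_count` column.
#' @param mode `"cell"` or `"embryo"`.
#' @return List with `retained` (records, with `excluded = FALSE`),
#'   `audit` (excluded records with a `reason` column) and the original
#'   `n_input`.
#' @export
apply_exclusions <- function(records, mode = c("cell", "embryo")) {
  mode <- match.arg(mode)
  if (mode == "cell") {
    drop <- records$n_xist_clouds > 2
    reason <- "more than two Xist objects"
  } else {
    drop <- records$huwe1_count == 0
    reason <- "no Huwe1 signal"
  }
  drop[is.na(drop)] <- FALSE
  retained <- records[!drop, , drop = FALSE]
  audit <- records[drop, , drop = FALSE]
  if (nrow(audit) > 0L) audit$reason <- reason
  else audit$reason <- character(0)
  retained$excluded <- rep(FALSE, nrow(retained))
  list(retained = retained, audit = audit, n_input = nrow(records))
}
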