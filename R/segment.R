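#' Gaussian smoothing
#'
#' Low-pass filter applied before thresholding to suppress shot noise.
#' `sigma = 0` is the identity. Filtering uses a circular boundary, so the
#' image mean is preserved.
#'
#' @param img A [pixel_image].
#' @param sigma Gaussian standard deviation in pixels (>= 0).
#' @return A smoothed [pixel_image].
#' @export
gaussian_smooth <- function(img, sigma) {
  stopifnot(inherits(img, "pixel_image"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("'sigma' must be a single non-negative number")
  if (sigma == 0) return(img)
  sm <- EBImage::gblur(img$values, sigma = sigma)
  # FFT filtering can produce tiny negative overshoot on a non-negative image
  pixel_image(pmax(as.matrix(sm), 0), img$pixel_size)
}

#' Otsu threshold on a 256-bin histogram
#'
#' Computes the intensity cut that maximises the between-class variance of
#' the image histogram, binned into 256 equal-width bins spanning the
#' intensity range. The returned value is a bin edge; foreground is
#' defined as intensities strictly greater than the threshold. When
#' several cuts attain the maximum, their edge positions are averaged.
#'
#' @param img A [pixel_image] with at least two distinct intensity values.
#' @param levels Number of histogram bins (default 256).
#' @return The threshold intensity (scalar).
#' @export
otsu_threshold <- function(img, levels = 256L) {
  stopifnot(inherits(img, "pixel_image"))
  v <- as.vector(img$values)
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("otsu_threshold: constant image has no threshold")
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  bin <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  h <- as.numeric(tabulate(bin, nbins = levels))
  centers <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w0 <- cumsum(h)
  w1 <- sum(h) - w0
  s0 <- cumsum(h * centers)
  mu0 <- s0 / w0
  mu1 <- (s0[levels] - s0) / w1
  # candidate cut after bin k, k = 1..levels-1; edge breaks[k+1]
  k <- seq_len(levels - 1L)
  bcv <- w0[k] * w1[k] * (mu0[k] - mu1[k])^2
  bcv[!is.finite(bcv)] <- -Inf
  best <- which(bcv == max(bcv))
  mean(breaks[best + 1L])
}

#' Parameters of the nucleus segmentation chain
#'
#' @param sigma Gaussian smoothing sd in pixels before thresholding.
#' @param dilate Binary dilation iterations applied to the thresholded
#'   mask (3x3 structuring element per iteration); 0 disables.
#' @param seed_separation Minimum separation (pixels) between watershed
#'   seeds, i.e. the radius used when merging nearby distance-map maxima.
#' @param tolerance Minimum distance-map depth separating two objects for
#'   the watershed to keep them apart.
#' @return A list of class `segment_params`.
#' @export
segment_params <- function(sigma = 2, dilate = 0, seed_separation = 10,
                           tolerance = 1) {
  stopifnot(sigma >= 0, dilate >= 0, seed_separation >= 1, tolerance > 0)
  structure(list(sigma = sigma, dilate = as.integer(dilate),
                 seed_separation = seed_separation, tolerance = tolerance),
            class = "segment_params")
}

#' Segment nuclei from a DNA-stain image
#'
#' The primary-object detection chain: Gaussian smooth, Otsu threshold
#' (foreground strictly above), hole filling, binary dilation, then a
#' distance-transform watershed that splits touching nuclei at the ridge
#' between their distance-map maxima.
#'
#' @param img A [pixel_image] of the DNA (DAPI) channel.
#' @param params A [segment_params] object.
#' @return A [label_map]; empty (all zero, with a warning) when no pixel
#'   exceeds the Otsu threshold or the image is constant.
#' @export
segment_nuclei <- function(img, params = segment_params()) {
  stopifnot(inherits(img, "pixel_image"), inherits(params, "segment_params"))
  sm <- gaussian_smooth(img, params$sigma)
  thr <- tryCatch(otsu_threshold(sm), error = function(e) NA_real_)
  if (is.na(thr)) {
    warning("segment_nuclei: constant image, no foreground")
    return(label_map(matrix(0L, nrow(img$values), ncol(img$values)),
                     img$pixel_size))
  }
  mask <- (sm$values > thr) * 1
  if (sum(mask) == 0) {
    warning("segment_nuclei: no foreground after thresholding")
    return(label_map(matrix(0L, nrow(img$values), ncol(img$values)),
                     img$pixel_size))
  }
  mask <- EBImage::fillHull(mask)
  if (params$dilate > 0) {
    kern <- EBImage::makeBrush(2L * params$dilate + 1L, shape = "disc")
    mask <- EBImage::dilate(mask, kern)
  }
  dm <- EBImage::distmap(mask)
  ws <- EBImage::watershed(dm, tolerance = params$tolerance,
                           ext = params$seed_separation)
  label_map(as.matrix(EBImage::imageData(ws)), img$pixel_size)
}

#' Maximal Feret diameter of an object mask
#'
#' The largest caliper distance across the object, computed over the
#' corner coordinates of its pixels (each pixel contributes its four
#' corners), so that a single pixel has Feret diameter `sqrt(2)` pixel
#' widths and thin objects keep a finite, non-zero circularity. The
#' maximum over corner pairs is taken on the convex hull.
#'
#' @param mask Logical (or 0/1) matrix marking the object's pixels.
#' @param pixel_size Pixel size in um/pixel.
#' @return Maximal Feret diameter in um.
#' @export
feret_max <- function(mask, pixel_size) {
  px <- which(mask != 0, arr.ind = TRUE)
  if (nrow(px) == 0L) stop("feret_max: empty mask")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("'pixel_size' must be positive")
  off <- cbind(c(-0.5, -0.5, 0.5, 0.5), c(-0.5, 0.5, -0.5, 0.5))
  corners <- unique(rbind(
    cbind(px[, 1] + off[1, 1], px[, 2] + off[1, 2]),
    cbind(px[, 1] + off[2, 1], px[, 2] + off[2, 2]),
    cbind(px[, 1] + off[3, 1], px[, 2] + off[3, 2]),
    cbind(px[, 1] + off[4, 1], px[, 2] + off[4, 2])))
  if (nrow(corners) > 3L) {
    hull <- grDevices::chull(corners[, 2], corners[, 1])
    corners <- corners[hull, , drop = FALSE]
  }
  sqrt(max(dist(corners)^2)) * pixel_size
}

#' Circularity shape descriptor
#'
#' `sqrt(4 * area / (pi * FeretMax^2))`: exactly 1 for an ideal disc and
#' smaller for elongated objects. Used with closed acceptance ranges to
#' reject mis-segmented or fused nuclei.
#'
#' @param area_um2 Object area in um^2 (> 0).
#' @param feret_max_um Maximal Feret diameter in um (> 0).
#' @return Dimensionless circularity.
#' @export
circularity <- function(area_um2, feret_max_um) {
  if (any(area_um2 <= 0) || any(feret_max_um <= 0))
    stop("circularity: area and Feret diameter must be positive")
  sqrt(4 * area_um2 / (pi * feret_max_um^2))
}

#' Per-object shape features of a label map
#'
#' @param labels A [label_map].
#' @return A data frame with one row per object: `label`, `area_um2`,
#'   `feret_max_um`, `circularity`, `centroid_row`, `centroid_col`
#'   (pixel coordinates, row/col order).
#' @export
object_features <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  lab <- labels$labels
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L)
    return(data.frame(label = integer(0), area_um2 = numeric(0),
                      feret_max_um = numeric(0), circularity = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0)))
  ps <- labels$pixel_size
  rows <- lapply(ids, function(id) {
    m <- lab == id
    px <- which(m, arr.ind = TRUE)
    area <- nrow(px) * ps^2
    fer <- feret_max(m, ps)
    data.frame(label = id, area_um2 = area, feret_max_um = fer,
               circularity = circularity(area, fer),
               centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]))
  })
  do.call(rbind, rows)
}

#' Filter objects by area and circularity
#'
#' Keeps objects whose area and circularity fall inside the closed
#' acceptance intervals. The conventional ranges are 100-450 um^2 with
#' circularity 0.7-1 for embryo nuclei and 50-300 um^2 with circularity
#' 0.5-1 for cultured-cell nuclei (see [filter_ranges()]).
#'
#' @param features Data frame from [object_features()].
#' @param area_range Numeric length-2, closed interval in um^2.
#' @param circ_range Numeric length-2, closed circularity interval.
#' @return Integer vector of retained labels.
#' @export
filter_objects <- function(features, area_range, circ_range) {
  stopifnot(length(area_range) == 2L, length(circ_range) == 2L,
            area_range[1] <= area_range[2], circ_range[1] <= circ_range[2])
  if (nrow(features) == 0L) return(integer(0))
  keep <- features$area_um2 >= area_range[1] &
    features$area_um2 <= area_range[2] &
    features$circularity >= circ_range[1] &
    features$circularity <= circ_range[2]
  as.integer(features$label[keep])
}

#' Default shape-filter ranges per experiment mode
#'
#' @param mode `"embryo"` (area 100-450 um^2, circularity 0.7-1) or
#'   `"cell"` (area 50-300 um^2, circularity 0.5-1).
#' @return List with elements `area` and `circ`.
#' @export
filter_ranges <- function(mode = c("cell", "embryo")) {
  mode <- match.arg(mode)
  if (mode == "embryo") list(area = c(100, 450), circ = c(0.7, 1))
  else list(area = c(50, 300), circ = c(0.5, 1))
}
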