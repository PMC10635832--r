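#' Pixel image with physical calibration
#'
#' The basic unit of all image operations: a 2D intensity matrix together
#' with its physical pixel size in micrometres per pixel. Intensities are
#' arbitrary fluorescence units and must be finite and non-negative.
#'
#' @param values Numeric matrix of intensities, indexed `[row, col]`.
#' @param pixel_size Physical pixel size in um/pixel (> 0).
#' @return An object of class `pixel_image` with elements `values` and
#'   `pixel_size`.
#' @examples
#' img <- pixel_image(matrix(runif(100), 10, 10), pixel_size = 0.25)
#' img$pixel_size
#' @export
pixel_image <- function(values, pixel_size) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (!all(is.finite(values)))
    stop("image intensities must be finite")
  if (any(values < 0))
    stop("image intensities must be non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (um/pixel)")
  structure(list(values = values, pixel_size = as.numeric(pixel_size)),
            class = "pixel_image")
}

#' @export
print.pixel_image <- function(x, ...) {
  cat(sprintf("<pixel_image> %d x %d px, %.4g um/px, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Z-stack of calibrated images
#'
#' An ordered list of equally shaped [pixel_image] slices with a fixed
#' axial spacing, as acquired by stepping the focal plane through the
#' specimen.
#'
#' @param slices List of `pixel_image` objects, all with identical shape
#'   and pixel size, ordered along the optical axis.
#' @param z_spacing Axial distance between consecutive slices in um (> 0).
#' @return An object of class `zstack`.
#' @export
zstack <- function(slices, z_spacing) {
  if (!is.list(slices) || length(slices) == 0L)
    stop("'slices' must be a non-empty list of pixel_image objects")
  if (!all(vapply(slices, inherits, logical(1), "pixel_image")))
    stop("every slice must be a pixel_image")
  dims <- vapply(slices, function(s) dim(s$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all slices must have the same shape")
  ps <- vapply(slices, function(s) s$pixel_size, numeric(1))
  if (any(ps != ps[1]))
    stop("all slices must share the same pixel_size")
  if (!is.numeric(z_spacing) || length(z_spacing) != 1L || z_spacing <= 0)
    stop("'z_spacing' must be a single positive number (um)")
  structure(list(slices = slices, z_spacing = as.numeric(z_spacing)),
            class = "zstack")
}

#' Maximum intensity projection
#'
#' Collapses a z-stack to a single 2D image by taking, at every pixel
#' position, the maximum intensity across all slices. All downstream
#' segmentation and quantification operates on the projected image.
#'
#' @param stack A [zstack].
#' @return A [pixel_image] with the same shape and pixel size as the
#'   slices.
#' @examples
#' s1 <- pixel_image(matrix(c(0, 2, 1, 3), 2, 2), 0.25)
#' s2 <- pixel_image(matrix(c(5, 1, 0, 2), 2, 2), 0.25)
#' max_project(zstack(list(s1, s2), z_spacing = 0.23))$values
#' @export
max_project <- function(stack) {
  if (!inherits(stack, "zstack")) stop("'stack' must be a zstack")
  out <- Reduce(pmax, lapply(stack$slices, `[[`, "values"))
  pixel_image(out, stack$slices[[1]]$pixel_size)
}

#' Axial extent of a z-stack
#'
#' Total height covered by an acquisition of `n_slices` focal planes at a
#' fixed spacing: the distance between the first and last plane,
#' `(n_slices - 1) * spacing`. For example, 62 slices at 0.23 um span
#' 14.03 um, slightly more than the height of an adherent ES cell.
#'
#' @param n_slices Number of slices (>= 2).
#' @param spacing Axial slice spacing in um (> 0).
#' @return Stack height in um.
#' @export
axial_extent <- function(n_slices, spacing) {
  if (!is.numeric(n_slices) || length(n_slices) != 1L || n_slices < 2)
    stop("'n_slices' must be a single number >= 2")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("'spacing' must be a single positive number")
  (n_slices - 1) * spacing
}

#' Integer label map of segmented objects
#'
#' @param labels Integer matrix; 0 is background, positive integers are
#'   object labels.
#' @param pixel_size Physical pixel size in um/pixel.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, pixel_size) {
  if (!is.matrix(labels)) stop("'labels' must be a matrix")
  lab <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  if (any(lab < 0L)) stop("labels must be non-negative integers")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number")
  structure(list(labels = lab, pixel_size = as.numeric(pixel_size)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d px, %d objects\n",
              nrow(x$labels), ncol(x$labels), max(x$labels)))
  invisible(x)
}
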