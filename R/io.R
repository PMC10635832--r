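# Plain-format I/O: multi-page float TIFF for images (channels in the
# fixed order DNA/GATA6/Xist/Huwe1), CSV for tables and metadata.

CHANNEL_ORDER <- c("DNA", "GATA6", "Xist", "Huwe1")

#' Write a field to disk
#'
#' Writes one multi-page 32-bit TIFF per field (channels in the fixed
#' order DNA, GATA6, Xist, Huwe1, restricted to those present), a
#' metadata CSV (channel names, pixel size, intensity scale) and, for
#' synthetic fields, the ground-truth tables.
#'
#' @param field A `synthetic_field` or named list of [pixel_image].
#' @param dir Output directory (created if needed).
#' @param name Base name for the files.
#' @return Invisibly, the TIFF path.
#' @export
write_field <- function(field, dir, name = "field") {
  channels <- field_channels(field)
  channels <- channels[intersect(CHANNEL_ORDER, names(channels))]
  if (length(channels) == 0L) stop("no recognised channels to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scale <- max(1, vapply(channels, function(ch) max(ch$values), numeric(1)))
  tif <- file.path(dir, paste0(name, ".tif"))
  tiff::writeTIFF(lapply(channels, function(ch) ch$values / scale),
                  tif, bits.per.sample = 32L)
  meta <- data.frame(key = c("channels", "pixel_size", "intensity_scale"),
                     value = c(paste(names(channels), collapse = ";"),
                               channels[[1]]$pixel_size, scale))
  utils::write.csv(meta, file.path(dir, paste0(name, "_meta.csv")),
                   row.names = FALSE)
  if (inherits(field, "synthetic_field")) {
    utils::write.csv(field$truth$nuclei,
                     file.path(dir, paste0(name, "_truth_nuclei.csv")),
                     row.names = FALSE)
    utils::write.csv(field$truth$clouds,
                     file.path(dir, paste0(name, "_truth_clouds.csv")),
                     row.names = FALSE)
  }
  invisible(tif)
}

#' Read a field written by [write_field()]
#'
#' @param dir Directory containing the files.
#' @param name Base name used at write time.
#' @return Named list of [pixel_image] channels.
#' @export
read_field <- function(dir, name = "field") {
  meta <- utils::read.csv(file.path(dir, paste0(name, "_meta.csv")),
                          colClasses = "character")
  get_meta <- function(k) meta$value[meta$key == k]
  ch_names <- strsplit(get_meta("channels"), ";", fixed = TRUE)[[1]]
  ps <- as.numeric(get_meta("pixel_size"))
  scale <- as.numeric(get_meta("intensity_scale"))
  pages <- tiff::readTIFF(file.path(dir, paste0(name, ".tif")), all = TRUE)
  if (length(pages) != length(ch_names))
    stop("TIFF page count does not match the channel list")
  stats::setNames(
    lapply(pages, function(p) pixel_image(p * scale, ps)), ch_names)
}

#' Read a flow-cytometry event table
#'
#' @param path CSV with one fluorescence column per event table.
#' @param column Name of the intensity column to use.
#' @param label Sample label (defaults to the file name).
#' @return A [flow_sample()].
#' @export
read_flow_csv <- function(path, column = "intensity", label = NULL) {
  df <- utils::read.csv(path)
  if (!column %in% names(df))
    stop(sprintf("column '%s' not found in %s", column, path))
  flow_sample(df[[column]],
              label = if (is.null(label)) basename(path) else label)
}

#' Write a flow sample as CSV
#'
#' @param sample A [flow_sample()].
#' @param path Output CSV path.
#' @param column Intensity column name.
#' @export
write_flow_csv <- function(sample, path, column = "intensity") {
  stopifnot(inherits(sample, "flow_sample"))
  df <- data.frame(x = sample$events)
  names(df) <- column
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Cq table
#'
#' @param path CSV with columns `primer_pair`, `line`, `replicate`, `Cq`.
#' @return Data frame suitable for [dosage_ratio()] / [classify_panel()].
#' @export
read_cq_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("primer_pair", "line", "Cq")
  if (!all(need %in% names(df)))
    stop("Cq table needs columns primer_pair, line, Cq")
  df
}
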