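# End-to-end orchestration: segment -> filter -> quantify -> statistics,
# with stage-count logging and a config hash stamped on every output.

#' Analysis run configuration
#'
#' Collects every tunable parameter of the analysis chain. Shape-filter
#' ranges default to the mode conventions (cell: 50-300 um^2,
#' circularity 0.5-1; embryo: 100-450 um^2, 0.7-1); the cytoplasmic ring
#' defaults to 30 px and cloud detection to a rolling-ball radius of
#' 20 px with a 1 px pre-smooth.
#'
#' @param mode `"cell"` or `"embryo"`.
#' @param cloud_threshold Fixed intensity threshold for Xist cloud
#'   detection (required; units of the smoothed background-subtracted
#'   image).
#' @param spot_threshold Threshold for Huwe1 focus detection (embryo
#'   mode).
#' @param segment A [segment_params()].
#' @param area_range,circ_range Shape-filter intervals; `NULL` uses the
#'   mode defaults from [filter_ranges()].
#' @param ring_width_px Cytoplasmic ring width in pixels.
#' @param min_ring_px Rings smaller than this many pixels are flagged
#'   and the cell's ratio set to `NA`.
#' @param cloud_smooth_sigma,ball_radius,cloud_min_area_px,spot_min_area_px
#'   Detection-chain parameters (see [cloud_params()]).
#' @param seed Integer seed recorded in all outputs.
#' @return A list of class `run_config` with a `hash` element.
#' @export
run_config <- function(mode = c("cell", "embryo"), cloud_threshold,
                       spot_threshold = NULL,
                       segment = segment_params(),
                       area_range = NULL, circ_range = NULL,
                       ring_width_px = 30, min_ring_px = 50,
                       cloud_smooth_sigma = 1, ball_radius = 20,
                       cloud_min_area_px = 5, spot_min_area_px = 2,
                       seed = 1L) {
  mode <- match.arg(mode)
  fr <- filter_ranges(mode)
  if (is.null(area_range)) area_range <- fr$area
  if (is.null(circ_range)) circ_range <- fr$circ
  if (mode == "embryo" && is.null(spot_threshold))
    stop("embryo mode requires a spot_threshold for Huwe1 detection")
  cfg <- list(mode = mode, cloud_threshold = cloud_threshold,
              spot_threshold = spot_threshold, segment = segment,
              area_range = area_range, circ_range = circ_range,
              ring_width_px = ring_width_px, min_ring_px = min_ring_px,
              cloud_smooth_sigma = cloud_smooth_sigma,
              ball_radius = ball_radius,
              cloud_min_area_px = cloud_min_area_px,
              spot_min_area_px = spot_min_area_px,
              seed = as.integer(seed))
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[setdiff(names(cfg), "hash")]), f)
  unname(tools::md5sum(f))
}

field_channels <- function(field) {
  if (inherits(field, "synthetic_field")) field$channels
  else if (is.list(field) && !is.null(field$channels)) field$channels
  else if (is.list(field) &&
           all(vapply(field, inherits, logical(1), "pixel_image"))) field
  else stop("field must be a synthetic_field or a named list of pixel_image")
}

xist_cloud_params <- function(config) {
  cloud_params(threshold = config$cloud_threshold,
               smooth_sigma = config$cloud_smooth_sigma,
               ball_radius = config$ball_radius,
               min_area_px = config$cloud_min_area_px,
               circ_range = if (config$mode == "cell") c(0.5, 1) else NULL)
}

huwe1_spot_params <- function(config) {
  cloud_params(threshold = config$spot_threshold,
               smooth_sigma = config$cloud_smooth_sigma,
               ball_radius = config$ball_radius,
               min_area_px = config$spot_min_area_px, circ_range = NULL)
}

# Segment one field's DNA channel and keep shape-filtered nuclei.
segment_and_filter <- function(channels, config) {
  labels <- segment_nuclei(channels$DNA, config$segment)
  feats <- object_features(labels)
  keep <- filter_objects(feats, config$area_range, config$circ_range)
  list(labels = labels, features = feats, keep = keep)
}

#' Run the cell-mode analysis end to end
#'
#' For every field: segment nuclei from the DNA channel, filter by area
#' and circularity, draw the cytoplasmic ring, measure the GATA6-HA
#' nuclear-to-cytoplasmic ratio, detect Xist clouds and their summed
#' intensities, exclude cells with more than two Xist objects, then
#' group cells by detected cloud count (0/1/2) and compare the per-group
#' nuc:cyt ratios with pairwise two-sided Wilcoxon rank-sum tests.
#'
#' @param fields List of fields; each a `synthetic_field` (from
#'   [generate_cell_field()]), a list with a `channels` element, or a
#'   named list of [pixel_image] with channels `DNA`, `GATA6`, `Xist`.
#' @param config A [run_config()] with `mode = "cell"`.
#' @return List of class `cell_analysis`: `cells` (all measured
#'   records), `retained`, `audit` (excluded records with reasons),
#'   `group_summaries` (per cloud count, [boxplot_summary()]), `tests`
#'   (pairwise Wilcoxon data frame), `log`, `config_hash`, `seed`.
#' @export
run_cell_analysis <- function(fields, config) {
  stopifnot(inherits(config, "run_config"), config$mode == "cell")
  cp <- xist_cloud_params(config)
  log <- character(0)
  records <- list()
  for (fi in seq_along(fields)) {
    channels <- field_channels(fields[[fi]])
    if (!all(c("DNA", "GATA6", "Xist") %in% names(channels)))
      stop(sprintf("field %d: need channels DNA, GATA6, Xist", fi))
    sf <- segment_and_filter(channels, config)
    log <- c(log, sprintf(
      "field %d: segmented %d object(s), %d passed shape filters",
      fi, nrow(sf$features), length(sf$keep)))
    if (length(sf$keep) == 0L) next
    clouds <- detect_clouds(channels$Xist, sf$labels, cp)
    own <- ring_ownership(sf$labels, config$ring_width_px)
    for (id in sf$keep) {
      nm <- sf$labels$labels == id
      ring <- tryCatch(cytoplasm_ring(sf$labels, id, config$ring_width_px,
                                      ownership = own),
                       xq_empty_ring = function(e) NULL)
      ring_ok <- !is.null(ring) && attr(ring, "n_px") >= config$min_ring_px
      if (!ring_ok)
        log <- c(log, sprintf(
          "field %d nucleus %d: cytoplasmic ring empty or too small, ratio set NA",
          fi, id))
      nuc_mean <- mean(channels$GATA6$values[nm])
      cyt_mean <- if (ring_ok) mean(channels$GATA6$values[ring]) else NA_real_
      cl <- clouds[clouds$nucleus == id, , drop = FALSE]
      records[[length(records) + 1L]] <- data.frame(
        field = fi, nucleus = id,
        area_um2 = sf$features$area_um2[sf$features$label == id],
        circularity = sf$features$circularity[sf$features$label == id],
        nuc_mean = nuc_mean, cyt_mean = cyt_mean,
        nuc_cyt_ratio = if (ring_ok && cyt_mean > 0) nuc_mean / cyt_mean
                        else NA_real_,
        n_xist_clouds = nrow(cl),
        xist_summed_intensity = if (nrow(cl)) sum(cl$summed_intensity) else 0,
        ring_flag = !ring_ok)
    }
  }
  cells <- if (length(records)) do.call(rbind, records) else
    data.frame(field = integer(0), nucleus = integer(0),
               area_um2 = numeric(0), circularity = numeric(0),
               nuc_mean = numeric(0), cyt_mean = numeric(0),
               nuc_cyt_ratio = numeric(0), n_xist_clouds = integer(0),
               xist_summed_intensity = numeric(0), ring_flag = logical(0))
  ex <- apply_exclusions(cells, "cell")
  log <- c(log, sprintf("exclusions: %d retained + %d excluded = %d input",
                        nrow(ex$retained), nrow(ex$audit), ex$n_input))
  ret <- ex$retained
  groups <- sort(unique(ret$n_xist_clouds))
  group_summaries <- lapply(stats::setNames(groups, groups), function(g) {
    v <- ret$nuc_cyt_ratio[ret$n_xist_clouds == g]
    boxplot_summary(v[!is.na(v)])
  })
  tests <- NULL
  if (length(groups) >= 2L) {
    pairs <- utils::combn(groups, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- ret$nuc_cyt_ratio[ret$n_xist_clouds == pairs[1, j]]
      b <- ret$nuc_cyt_ratio[ret$n_xist_clouds == pairs[2, j]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) == 0L || length(b) == 0L) return(NULL)
      w <- wilcoxon_rank_sum(a, b)
      data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
                 n_a = length(a), n_b = length(b),
                 statistic = w$statistic, p_value = w$p_value,
                 method = w$method)
    }))
  }
  structure(list(cells = cells, retained = ret, audit = ex$audit,
                 group_summaries = group_summaries, tests = tests,
                 log = log, config_hash = config$hash, seed = config$seed),
            class = "cell_analysis")
}

#' Run the embryo-mode analysis end to end
#'
#' Each embryo field is segmented and shape-filtered, sexed from the
#' per-nucleus Huwe1 nascent-transcript counts (two signals female, one
#' male), and male or ambiguous embryos are dropped with a log entry.
#' In the remaining female embryos Xist clouds are detected (no
#' circularity filter in embryo mode), nuclei without a Huwe1 signal are
#' excluded, and the per-cell summed Xist intensities are compared
#' between conditions with a two-sided Wilcoxon rank-sum test.
#'
#' @param fields List of embryo fields (see [run_cell_analysis()] for
#'   accepted forms; channels `DNA`, `Xist`, `Huwe1`).
#' @param conditions Character vector of condition labels, one per field.
#' @param config A [run_config()] with `mode = "embryo"`.
#' @return List of class `embryo_analysis`: `embryos` (id, condition,
#'   sex call, inclusion), `cells` (retained per-nucleus records),
#'   `audit`, `tests` (pairwise Wilcoxon on summed Xist intensity),
#'   `log`, `config_hash`, `seed`. Raises an error if any condition ends
#'   up with no female embryo.
#' @export
run_embryo_analysis <- function(fields, conditions, config) {
  stopifnot(inherits(config, "run_config"), config$mode == "embryo",
            length(fields) == length(conditions))
  cp <- xist_cloud_params(config)
  sp <- huwe1_spot_params(config)
  log <- character(0)
  embryos <- list()
  records <- list()
  for (fi in seq_along(fields)) {
    channels <- field_channels(fields[[fi]])
    if (!all(c("DNA", "Xist", "Huwe1") %in% names(channels)))
      stop(sprintf("field %d: need channels DNA, Xist, Huwe1", fi))
    sf <- segment_and_filter(channels, config)
    log <- c(log, sprintf(
      "embryo %d: segmented %d object(s), %d passed shape filters",
      fi, nrow(sf$features), length(sf$keep)))
    if (length(sf$keep) == 0L) {
      embryos[[fi]] <- data.frame(embryo = fi, condition = conditions[fi],
                                  sex = "ambiguous", n_nuclei = 0L,
                                  included = FALSE)
      log <- c(log, sprintf("embryo %d: no nuclei passed filters, dropped", fi))
      next
    }
    hc <- huwe1_counts(channels$Huwe1, sf$labels, sp)
    hc <- hc[hc$nucleus %in% sf$keep, , drop = FALSE]
    sex <- embryo_sex(hc$huwe1_count)
    included <- sex == "female"
    embryos[[fi]] <- data.frame(embryo = fi, condition = conditions[fi],
                                sex = sex, n_nuclei = length(sf$keep),
                                included = included)
    if (!included) {
      log <- c(log, sprintf("embryo %d: sexed %s, dropped", fi, sex))
      next
    }
    clouds <- detect_clouds(channels$Xist, sf$labels, cp)
    for (id in sf$keep) {
      cl <- clouds[clouds$nucleus == id, , drop = FALSE]
      records[[length(records) + 1L]] <- data.frame(
        embryo = fi, condition = conditions[fi], nucleus = id,
        huwe1_count = hc$huwe1_count[hc$nucleus == id],
        n_xist_clouds = nrow(cl),
        xist_summed_intensity = if (nrow(cl)) sum(cl$summed_intensity) else 0)
    }
  }
  embryos <- do.call(rbind, embryos)
  for (cond in unique(conditions))
    if (!any(embryos$included & embryos$condition == cond))
      stop(sprintf("no female embryos in condition '%s'", cond))
  cells <- do.call(rbind, records)
  ex <- apply_exclusions(cells, "embryo")
  log <- c(log, sprintf("exclusions: %d retained + %d excluded = %d input",
                        nrow(ex$retained), nrow(ex$audit), ex$n_input))
  ret <- ex$retained
  conds <- unique(ret$condition)
  tests <- NULL
  if (length(conds) >= 2L) {
    pairs <- utils::combn(conds, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- ret$xist_summed_intensity[ret$condition == pairs[1, j]]
      b <- ret$xist_summed_intensity[ret$condition == pairs[2, j]]
      w <- wilcoxon_rank_sum(a, b)
      data.frame(condition_a = pairs[1, j], condition_b = pairs[2, j],
                 n_a = length(a), n_b = length(b),
                 statistic = w$statistic, p_value = w$p_value,
                 method = w$method)
    }))
  }
  structure(list(embryos = embryos, cells = ret, audit = ex$audit,
                 tests = tests, log = log, config_hash = config$hash,
                 seed = config$seed),
            class = "embryo_analysis")
}
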