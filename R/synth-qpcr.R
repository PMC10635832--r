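#' Simulate a genomic qPCR panel for transgene-boundary mapping
#'
#' Builds a Cq table for a transgenic XY line carrying one extra copy of
#' every "internal" locus (so two copies total) and a reference XY line
#' with one copy of everything, both normalised to a single-copy X-linked
#' locus outside the transgene. Perfect doubling per cycle is assumed, so
#' an internal locus sits one cycle lower in the transgenic line.
#'
#' @param n_internal,n_external Numbers of planted internal / external
#'   primer pairs.
#' @param n_replicates Technical replicates per (primer pair, line).
#' @param cq_noise_sd Gaussian noise sd on each Cq value, cycles.
#' @param base_cq_range Range the per-locus single-copy Cq values are
#'   drawn from, cycles.
#' @param transgenic_line,reference_line,normalizer Identifiers written
#'   into the table.
#' @param seed Integer seed.
#' @return List with `panel` (data frame: `primer_pair`, `line`,
#'   `replicate`, `Cq`) and `truth` (data frame: `primer_pair`,
#'   `is_internal`).
#' @export
generate_qpcr_panel <- function(n_internal = 5L, n_external = 5L,
                                n_replicates = 3L, cq_noise_sd = 0.15,
                                base_cq_range = c(22, 28),
                                transgenic_line = "XY-tg",
                                reference_line = "XY-ref",
                                normalizer = "norm_X",
                                seed = 1L) {
  stopifnot(n_internal >= 0L, n_external >= 0L, n_replicates >= 1L,
            cq_noise_sd >= 0)
  run_seeded(seed, {
    primers <- c(if (n_internal > 0) paste0("int_", seq_len(n_internal)),
                 if (n_external > 0) paste0("ext_", seq_len(n_external)))
    is_internal <- c(rep(TRUE, n_internal), rep(FALSE, n_external))
    base <- runif(length(primers), base_cq_range[1], base_cq_range[2])
    norm_base <- 25
    rows <- list()
    for (i in seq_along(primers)) {
      # one extra copy halves Cq_target by one cycle in the transgenic line
      cq_tg <- base[i] - if (is_internal[i]) 1 else 0
      rows[[length(rows) + 1L]] <- data.frame(
        primer_pair = primers[i],
        line = rep(c(transgenic_line, reference_line), each = n_replicates),
        replicate = rep(seq_len(n_replicates), 2L),
        Cq = c(cq_tg + rnorm(n_replicates, 0, cq_noise_sd),
               base[i] + rnorm(n_replicates, 0, cq_noise_sd)))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      primer_pair = normalizer,
      line = rep(c(transgenic_line, reference_line), each = n_replicates),
      replicate = rep(seq_len(n_replicates), 2L),
      Cq = norm_base + rnorm(2L * n_replicates, 0, cq_noise_sd))
    list(panel = do.call(rbind, rows),
         truth = data.frame(primer_pair = primers, is_internal = is_internal))
  })
}
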