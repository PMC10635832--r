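# Transgene-boundary mapping from genomic qPCR dosage ratios: a locus
# inside a single-copy transgene is present at two copies in the
# transgenic XY line versus one in the reference XY line (ratio ~2);
# a locus outside is at one copy in both (ratio ~1).

#' Relative quantity from a Cq difference
#'
#' Converts a target/normalizer Cq difference into a relative quantity
#' assuming perfect doubling per cycle: `2^-(Cq_target - Cq_norm)`.
#'
#' @param cq_target,cq_norm Finite Cq values (cycles).
#' @return Dimensionless relative quantity.
#' @export
relative_quantity <- function(cq_target, cq_norm) {
  if (!all(is.finite(cq_target)) || !all(is.finite(cq_norm)))
    stop("Cq values must be finite")
  2^-(cq_target - cq_norm)
}

mean_cq <- function(panel, primer, line) {
  v <- panel$Cq[panel$primer_pair == primer & panel$line == line]
  if (length(v) == 0L)
    stop(sprintf("no Cq measurements for primer '%s' in line '%s'",
                 primer, line))
  mean(v)
}

#' Between-line dosage ratio of a genomic locus
#'
#' Within each line, the target's relative quantity is computed against
#' the normalizer locus (a single-copy X-linked locus outside the
#' transgene); the dosage ratio is the transgenic-line quantity divided
#' by the reference-line quantity. Technical replicates are averaged on
#' the Cq scale first.
#'
#' @param panel Data frame with columns `primer_pair`, `line`,
#'   `replicate`, `Cq`.
#' @param primer_pair Target primer-pair id.
#' @param normalizer Normalizer primer-pair id.
#' @param transgenic_line,reference_line Line ids present in `panel`.
#' @return Dimensionless dosage ratio (~2 internal, ~1 external).
#' @export
dosage_ratio <- function(panel, primer_pair, normalizer,
                         transgenic_line, reference_line) {
  stopifnot(all(c("primer_pair", "line", "Cq") %in% names(panel)))
  rq_tg <- relative_quantity(mean_cq(panel, primer_pair, transgenic_line),
                             mean_cq(panel, normalizer, transgenic_line))
  rq_ref <- relative_quantity(mean_cq(panel, primer_pair, reference_line),
                              mean_cq(panel, normalizer, reference_line))
  rq_tg / rq_ref
}

#' Classify a genomic position from its dosage ratio
#'
#' A locus with ratio near 2 lies inside the transgene (two copies in
#' the transgenic line), near 1 outside. The default decision band calls
#' `internal` at ratio >= 1.5 and `external` at ratio <= 1.35, with an
#' `indeterminate` band in between rather than a hard binary.
#'
#' @param ratio Positive dosage ratio.
#' @param cutoffs Length-2 numeric `c(external_high, internal_low)`:
#'   ratios `<= cutoffs[1]` are external, `>= cutoffs[2]` internal.
#' @return `"internal"`, `"external"` or `"indeterminate"`.
#' @export
classify_position <- function(ratio, cutoffs = c(1.35, 1.5)) {
  if (any(ratio <= 0)) stop("dosage ratio must be positive")
  stopifnot(length(cutoffs) == 2L, cutoffs[1] <= cutoffs[2])
  ifelse(ratio >= cutoffs[2], "internal",
         ifelse(ratio <= cutoffs[1], "external", "indeterminate"))
}

#' Classify every primer pair of a qPCR panel
#'
#' @param panel Data frame (`primer_pair`, `line`, `replicate`, `Cq`).
#' @param normalizer Normalizer primer-pair id (excluded from the output).
#' @param transgenic_line,reference_line Line ids.
#' @param cutoffs Passed to [classify_position()].
#' @return Data frame `primer_pair`, `dosage_ratio`, `call`.
#' @export
classify_panel <- function(panel, normalizer, transgenic_line,
                           reference_line, cutoffs = c(1.35, 1.5)) {
  primers <- setdiff(unique(panel$primer_pair), normalizer)
  ratio <- vapply(primers, function(p)
    dosage_ratio(panel, p, normalizer, transgenic_line, reference_line),
    numeric(1))
  data.frame(primer_pair = primers, dosage_ratio = unname(ratio),
             call = classify_position(unname(ratio), cutoffs),
             row.names = NULL)
}
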