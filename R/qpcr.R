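## qRT-PCR validation arithmetic: relative abundance from Ct values,
## expected abundance from region-restricted sequencing counts, and their
## correlation.

#' qRT-PCR relative abundance
#'
#' \code{RA = 100 x 2^-(Ct_target - Ct_reference)} with the reference the
#' housekeeping gene (Actin2) amplicon. Adding a constant to both Ct values
#' leaves RA unchanged.
#'
#' @param ct_target,ct_reference threshold cycles.
#' @export
relative_abundance <- function(ct_target, ct_reference) {
  stopifnot(all(is.finite(ct_target)), all(is.finite(ct_reference)))
  100 * 2^-(ct_target - ct_reference)
}

#' Sequencing expected abundance
#'
#' \code{EA = 100 x} (m6A-seq fragments of the test gene within the qPCR
#' amplicon region / mRNA-seq fragments of the reference gene within its
#' amplicon region).
#'
#' @param m6a_reads_in_amplicon region-restricted m6A-seq count of the test
#'   gene.
#' @param reference_mrna_reads_in_amplicon region-restricted mRNA-seq count
#'   of the reference gene (> 0).
#' @export
expected_abundance <- function(m6a_reads_in_amplicon,
                               reference_mrna_reads_in_amplicon) {
  if (any(reference_mrna_reads_in_amplicon <= 0))
    stop("reference reads must be > 0")
  100 * m6a_reads_in_amplicon / reference_mrna_reads_in_amplicon
}

#' Count fragments overlapping a transcript region
#'
#' Projects a library onto the transcript models and counts the fragments
#' whose projection overlaps the given transcript-coordinate interval
#' (0-based half-open) — the region-restricted counts that feed
#' \code{\link{expected_abundance}}.
#'
#' @param lib a \code{\link{fragment_library}}.
#' @param models a \code{\link{transcript_models}} object.
#' @param transcript_id transcript of interest.
#' @param region integer \code{c(start, end)}, transcript coordinates.
#' @export
count_region_fragments <- function(lib, models, transcript_id, region) {
  pr <- project_fragments(lib$fragments, models)
  pr <- pr[pr$transcript_id == transcript_id, ]
  sum(pr$start < region[2] & pr$end > region[1])
}

#' Correlate qRT-PCR and sequencing abundances
#'
#' Pearson correlation of paired (RA, EA) values with a Fisher-z 95\%
#' confidence interval, optionally on log-transformed values.
#'
#' @param ra,ea paired relative and expected abundances (n >= 3).
#' @param log10_transform correlate on log10 values.
#' @return list: \code{r}, \code{n}, \code{conf_int} (length 2),
#'   \code{p_value}; all \code{NA} with a \code{degenerate} flag when either
#'   vector has zero variance.
#' @export
validate_correlation <- function(ra, ea, log10_transform = FALSE) {
  stopifnot(length(ra) == length(ea), length(ra) >= 3)
  if (log10_transform) { ra <- log10(ra); ea <- log10(ea) }
  if (stats::sd(ra) == 0 || stats::sd(ea) == 0)
    return(list(r = NA_real_, n = length(ra),
                conf_int = c(NA_real_, NA_real_), p_value = NA_real_,
                degenerate = TRUE))
  ct <- stats::cor.test(ra, ea, method = "pearson")
  list(r = unname(ct$estimate), n = length(ra),
       conf_int = as.numeric(ct$conf.int), p_value = ct$p.value,
       degenerate = FALSE)
}
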