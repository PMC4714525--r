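## Per-transcript quantification: FPKM for mRNA-seq, MFPKM (covered-length
## normalized) for m6A-seq, the covered-length/150 peak-count estimator, and
## transcriptome summaries.

#' Union length of projected intervals
#'
#' Length of the union of a set of transcript-coordinate intervals — the
#' "total absolute mapped length covered by m6A fragments within the
#' transcript" that replaces transcript length in MFPKM.
#'
#' @param start,end integer vectors, 0-based half-open transcript intervals.
#' @return total covered length (nt).
#' @export
covered_length <- function(start, end = NULL) {
  if (is.data.frame(start)) { end <- start$end; start <- start$start }
  if (length(start) == 0) return(0L)
  stopifnot(all(end > start))
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start + 1L, end))))
}

#' FPKM
#'
#' \code{count * 1e9 / (transcript_length * total_mapped)}: fragments per
#' kilobase of transcript per million mapped fragments.
#'
#' @param count mapped fragments of the transcript.
#' @param transcript_length spliced transcript length (nt).
#' @param total_mapped library-wide mapped fragment total.
#' @export
compute_fpkm <- function(count, transcript_length, total_mapped) {
  if (any(transcript_length <= 0)) stop("transcript_length must be > 0")
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  count * 1e9 / (transcript_length * total_mapped)
}

#' MFPKM
#'
#' The m6A-seq analogue of FPKM with transcript length replaced by the m6A
#' covered length, reflecting that the immunoprecipitated library derives
#' only from site-bearing fragments, not whole transcripts:
#' \code{count * 1e9 / (covered_length * total_m6a_mapped)}. A zero count
#' gives 0 by convention.
#'
#' @param count m6A-seq fragments of the transcript.
#' @param covered_length m6A covered length (nt), see
#'   \code{\link{covered_length}}.
#' @param total_m6a_mapped m6A-seq library total.
#' @export
compute_mfpkm <- function(count, covered_length, total_m6a_mapped) {
  if (any(total_m6a_mapped <= 0)) stop("total_m6a_mapped must be > 0")
  if (any(count > 0 & covered_length <= 0))
    stop("positive count with zero covered length")
  ifelse(count == 0, 0, count * 1e9 / (covered_length * total_m6a_mapped))
}

#' Estimated m6A peak (site) count
#'
#' \code{round(covered_length / 150)}, floored at 1 for any positive
#' coverage: the average m6A peak spans ~150 nt, and a methylated transcript
#' must report at least one site.
#'
#' @param covered_length m6A covered length (nt).
#' @export
estimate_peak_count <- function(covered_length) {
  stopifnot(all(covered_length >= 0))
  as.integer(ifelse(covered_length == 0, 0L,
                    pmax(1L, round(covered_length / 150))))
}

#' Quantify one organ/replicate
#'
#' Projects the m6A-seq and mRNA-seq libraries of one \{organ, replicate\}
#' onto the transcript models and computes the full per-transcript record:
#' fragment counts, FPKM, covered length, MFPKM and estimated peak count.
#'
#' @param m6a_lib,mrna_lib \code{\link{fragment_library}} objects (assays
#'   \code{"m6A"} and \code{"mRNA"} of the same organ/replicate).
#' @param models a \code{\link{transcript_models}} object.
#' @return data.frame with one row per transcript: \code{transcript_id},
#'   \code{organ}, \code{replicate}, \code{mrna_count}, \code{m6a_count},
#'   \code{fpkm}, \code{covered_length}, \code{mfpkm}, \code{peak_count}.
#' @export
quantify <- function(m6a_lib, mrna_lib, models) {
  stopifnot(m6a_lib$assay == "m6A", mrna_lib$assay == "mRNA")
  ids <- models$tx$transcript_id
  pm <- project_fragments(m6a_lib$fragments, models)
  pr <- project_fragments(mrna_lib$fragments, models)
  m6a_count <- as.integer(table(factor(pm$transcript_id, levels = ids)))
  mrna_count <- as.integer(table(factor(pr$transcript_id, levels = ids)))
  cov <- integer(length(ids))
  if (nrow(pm)) {
    ir <- IRanges::IRanges(pm$start + 1L, pm$end)
    irl <- IRanges::reduce(S4Vectors::split(ir, factor(pm$transcript_id,
                                                       levels = ids)))
    cov <- as.integer(sum(IRanges::width(irl)))
  }
  data.frame(
    transcript_id = ids,
    organ = m6a_lib$organ,
    replicate = m6a_lib$replicate,
    mrna_count = mrna_count,
    m6a_count = m6a_count,
    fpkm = if (mrna_lib$total_mapped > 0)
      compute_fpkm(mrna_count, models$tx$tx_len, mrna_lib$total_mapped)
      else 0,
    covered_length = cov,
    mfpkm = if (m6a_lib$total_mapped > 0)
      compute_mfpkm(m6a_count, cov, m6a_lib$total_mapped) else 0,
    peak_count = estimate_peak_count(cov),
    stringsAsFactors = FALSE)
}

#' Transcriptome-level m6A summary
#'
#' Methylated = any m6A fragment; transcribed = any mRNA fragment. Site
#' counts use the estimated peak count; the m6A/A ratio divides total
#' estimated sites by the adenosine count of the transcript sequences of the
#' respective set (methylated or transcribed), as a percentage.
#'
#' @param quant output of \code{\link{quantify}} for one organ/replicate.
#' @param models a \code{\link{transcript_models}} object.
#' @param genome named \code{DNAStringSet}; required for the m6A/A ratios
#'   (omit with \code{NULL} to skip them).
#' @return one-row data.frame: \code{n_methylated},
#'   \code{proportion_methylated} (\% of transcribed),
#'   \code{total_peaks}, \code{sites_per_methylated_transcript},
#'   \code{sites_per_transcript}, \code{m6a_to_A_ratio_methylated} (\%),
#'   \code{m6a_to_A_ratio_all} (\%).
#' @export
summarize_transcriptome <- function(quant, models, genome = NULL) {
  meth <- quant$m6a_count > 0
  trans <- quant$mrna_count > 0
  if (!any(trans)) stop("empty transcribed set")
  n_meth <- sum(meth)
  total_peaks <- sum(quant$peak_count)
  ratio_meth <- ratio_all <- NA_real_
  if (!is.null(genome)) {
    seqs <- transcript_sequences(genome, models)
    a_counts <- stats::setNames(Biostrings::letterFrequency(seqs, "A")[, 1],
                                names(seqs))
    a_counts <- a_counts[match(quant$transcript_id, names(a_counts))]
    ratio_meth <- if (n_meth > 0)
      sum(quant$peak_count[meth]) / sum(a_counts[meth]) * 100 else 0
    ratio_all <- sum(quant$peak_count[trans]) / sum(a_counts[trans]) * 100
  }
  data.frame(
    n_methylated = n_meth,
    proportion_methylated = n_meth / sum(trans) * 100,
    total_peaks = total_peaks,
    sites_per_methylated_transcript =
      if (n_meth > 0) sum(quant$peak_count[meth]) / n_meth else 0,
    sites_per_transcript = sum(quant$peak_count[trans]) / sum(trans),
    m6a_to_A_ratio_methylated = ratio_meth,
    m6a_to_A_ratio_all = ratio_all)
}
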