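## Between-organ differential methylation (NFPKM) and differential expression
## (FPKM): fold change + chi-square + BH FDR, organ-specific sets, replicate
## agreement, and the fold-change matrix export.

#' NFPKM: expression-damped methylation statistic
#'
#' \code{NFPKM = MFPKM / log2(FPKM)}. Transcripts with FPKM <= 1 are excluded
#' (\code{NA}) because the log2 denominator would be zero or negative; the
#' exclusion is reported, never silently dropped.
#'
#' @param mfpkm,fpkm vectors from \code{\link{quantify}}.
#' @return numeric vector; \code{NA} flags exclusion.
#' @export
compute_nfpkm <- function(mfpkm, fpkm) {
  ifelse(fpkm > 1, mfpkm / log2(pmax(fpkm, 1 + 1e-12)), NA_real_)
}

#' Differential-call thresholds
#'
#' Defaults follow the main analysis (fold > 2 or < 0.5, FDR < 0.05). The
#' extreme organ-specific preset is \code{dm_thresholds(10, 0.1, 1e-10, 20)};
#' alternative FDR presets 0.02 (expression) and 0.005 (methylation) are
#' sometimes used for pathway-level filtering.
#'
#' @param fold_hi upper fold threshold (> 1).
#' @param fold_lo lower fold threshold (between 0 and 1).
#' @param fdr_max FDR ceiling.
#' @param min_reads minimum m6A fragment count in both organs (0 = off).
#' @export
dm_thresholds <- function(fold_hi = 2, fold_lo = 0.5, fdr_max = 0.05,
                          min_reads = 0) {
  stopifnot(fold_hi > 1, fold_lo > 0, fold_lo < 1,
            fdr_max > 0, fdr_max < 1)
  list(fold_hi = fold_hi, fold_lo = fold_lo, fdr_max = fdr_max,
       min_reads = min_reads)
}

#' Differential test between two organs
#'
#' Pairs the per-transcript values of two organs (same replicate), computes
#' fold change a/b and the chi-square statistic of
#' \code{\link{ratio_chi_square}} applied to the two values, adjusts p-values
#' by Benjamini-Hochberg across all tested transcripts of the pair, and
#' assigns a direction per the thresholds. For metric \code{"NFPKM"}
#' (differential methylation) only m6A-modified transcripts with FPKM > 1 in
#' both organs are tested; exclusions are reported with a reason.
#'
#' @param quant_a,quant_b \code{\link{quantify}} outputs for the two organs
#'   (one replicate each).
#' @param metric \code{"NFPKM"} (differential m6A methylation) or
#'   \code{"FPKM"} (differential transcript level).
#' @param thresholds a \code{\link{dm_thresholds}} list.
#' @return data.frame with \code{transcript_id}, \code{organ_a},
#'   \code{organ_b}, \code{replicate}, \code{metric}, \code{value_a},
#'   \code{value_b}, \code{fold_change}, \code{chi2}, \code{p_value},
#'   \code{fdr}, \code{direction} (\code{higher_in_a} / \code{higher_in_b} /
#'   \code{not_significant}) and \code{excluded} (reason or \code{NA}).
#' @export
differential_test <- function(quant_a, quant_b, metric = c("NFPKM", "FPKM"),
                              thresholds = dm_thresholds()) {
  metric <- match.arg(metric)
  shared <- intersect(quant_a$transcript_id, quant_b$transcript_id)
  if (length(shared) == 0) stop("empty shared transcript set")
  a <- quant_a[match(shared, quant_a$transcript_id), ]
  b <- quant_b[match(shared, quant_b$transcript_id), ]
  out <- data.frame(transcript_id = shared,
                    organ_a = a$organ[1], organ_b = b$organ[1],
                    replicate = a$replicate[1], metric = metric,
                    stringsAsFactors = FALSE)
  excluded <- rep(NA_character_, length(shared))
  if (metric == "NFPKM") {
    va <- compute_nfpkm(a$mfpkm, a$fpkm)
    vb <- compute_nfpkm(b$mfpkm, b$fpkm)
    excluded[a$m6a_count == 0 | b$m6a_count == 0] <- "not_methylated"
    low <- is.na(excluded) & (is.na(va) | is.na(vb))
    excluded[low] <- "fpkm_below_1"
  } else {
    va <- a$fpkm
    vb <- b$fpkm
  }
  excluded[is.na(excluded) & (is.na(va + vb) | va + vb <= 0)] <- "no_signal"
  tested <- is.na(excluded)
  out$value_a <- va
  out$value_b <- vb
  out$fold_change <- ifelse(tested & vb > 0, va / vb, NA_real_)
  out$chi2 <- NA_real_
  out$p_value <- NA_real_
  if (any(tested)) {
    cs <- ratio_chi_square(va[tested], vb[tested])
    out$chi2[tested] <- cs$chi2
    out$p_value[tested] <- cs$p_value
  }
  out$fdr <- NA_real_
  out$fdr[tested] <- stats::p.adjust(out$p_value[tested], method = "fdr")
  reads_ok <- if (thresholds$min_reads > 0)
    pmin(a$m6a_count, b$m6a_count) >= thresholds$min_reads else TRUE
  out$direction <- "not_significant"
  sig <- tested & !is.na(out$fold_change) & out$fdr < thresholds$fdr_max &
    reads_ok
  out$direction[sig & out$fold_change > thresholds$fold_hi] <- "higher_in_a"
  out$direction[sig & out$fold_change < thresholds$fold_lo] <- "higher_in_b"
  out$excluded <- excluded
  out
}

#' Summarize differential calls for one organ pair
#'
#' @param calls output of \code{\link{differential_test}}.
#' @return one-row data.frame with counts and percentages per direction over
#'   the tested transcripts, and their total.
#' @export
summarize_differential <- function(calls) {
  tested <- is.na(calls$excluded)
  n <- sum(tested)
  n_a <- sum(calls$direction == "higher_in_a")
  n_b <- sum(calls$direction == "higher_in_b")
  data.frame(organ_a = calls$organ_a[1], organ_b = calls$organ_b[1],
             replicate = calls$replicate[1], metric = calls$metric[1],
             n_tested = n,
             higher_in_a = n_a, higher_in_b = n_b,
             pct_higher_in_a = n_a / n * 100,
             pct_higher_in_b = n_b / n * 100,
             pct_total = (n_a + n_b) / n * 100)
}

#' Organ-specific differential sets
#'
#' Transcripts with a higher value in the focal organ than in \emph{both}
#' other organs, in \emph{every} replicate (common-elements rule).
#'
#' @param calls row-bound \code{\link{differential_test}} outputs covering
#'   all organ pairs and replicates.
#' @return named list (per organ) of transcript id vectors.
#' @export
organ_specific_sets <- function(calls) {
  organs <- unique(c(calls$organ_a, calls$organ_b))
  reps <- unique(calls$replicate)
  out <- lapply(organs, function(o) {
    others <- setdiff(organs, o)
    per_rep <- lapply(reps, function(r) {
      cr <- calls[calls$replicate == r, ]
      per_other <- lapply(others, function(oo) {
        up_a <- cr$organ_a == o & cr$organ_b == oo &
          cr$direction == "higher_in_a"
        up_b <- cr$organ_b == o & cr$organ_a == oo &
          cr$direction == "higher_in_b"
        cr$transcript_id[up_a | up_b]
      })
      Reduce(intersect, per_other)
    })
    Reduce(intersect, per_rep)
  })
  names(out) <- organs
  out
}

#' Replicate agreement
#'
#' Overlap of two transcript sets as a percentage of each set and of their
#' union; the headline agreement statistic is the smaller of the two
#' per-set percentages.
#'
#' @param set_a,set_b character vectors of transcript ids.
#' @return list with \code{pct_a}, \code{pct_b}, \code{pct_union},
#'   \code{headline}; all \code{NA} when both sets are empty.
#' @export
replicate_agreement <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) == 0 && length(set_b) == 0)
    return(list(pct_a = NA_real_, pct_b = NA_real_, pct_union = NA_real_,
                headline = NA_real_))
  ov <- length(intersect(set_a, set_b))
  pct_a <- if (length(set_a)) ov / length(set_a) * 100 else 0
  pct_b <- if (length(set_b)) ov / length(set_b) * 100 else 0
  list(pct_a = pct_a, pct_b = pct_b,
       pct_union = ov / length(union(set_a, set_b)) * 100,
       headline = min(pct_a, pct_b))
}

#' Fold-change matrix for heatmap export
#'
#' log2 fold changes, transcripts x organ pairs, rows in alphabetic gene-id
#' order (which in the AT<chr>G<pos> naming walks chromosomes 1 to 5 in
#' positional order). Missing or excluded entries are \code{NA}.
#'
#' @param calls row-bound \code{\link{differential_test}} outputs (one
#'   replicate).
#' @return numeric matrix; columns named \code{"<organ_a>_vs_<organ_b>"}.
#' @export
fold_change_matrix <- function(calls) {
  pair <- paste0(calls$organ_a, "_vs_", calls$organ_b)
  ids <- sort(unique(calls$transcript_id))
  cols <- unique(pair)
  m <- matrix(NA_real_, length(ids), length(cols),
              dimnames = list(ids, cols))
  m[cbind(match(calls$transcript_id, ids), match(pair, cols))] <-
    log2(calls$fold_change)
  m
}
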