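## Metagene topology and motif analysis: 60-bin profiles, peak extraction
## from per-base coverage, Type 1 / Type 2 classification, and the RRACH
## consensus tally over the top peaks.

## per-transcript coverage (RleList over transcript coordinates) from
## projected fragments
.tx_coverage <- function(lib, models) {
  pr <- project_fragments(lib$fragments, models)
  ids <- models$tx$transcript_id
  ir <- IRanges::IRanges(pr$start + 1L, pr$end)
  irl <- S4Vectors::split(ir, factor(pr$transcript_id, levels = ids))
  IRanges::coverage(irl, width = stats::setNames(models$tx$tx_len, ids))
}

#' Metagene profile
#'
#' Each transcript's spliced length is divided into \code{n_bins} equal bins
#' from 5' (bin 0, the TSS end) to 3' (last bin); per-bin read depth is
#' normalized per 1 kb of bin width per 1 Mb of library total
#' (\code{mean depth x 1e3 x 1e6 / total_mapped}), then averaged across
#' transcripts. Transcripts shorter than \code{n_bins} nt are skipped.
#'
#' @param lib a \code{\link{fragment_library}}.
#' @param models a \code{\link{transcript_models}} object.
#' @param n_bins number of bins (default 60).
#' @param covered_only average only over transcripts with any coverage.
#' @return object of class \code{metagene_profile}: list with \code{bins}
#'   (numeric, length \code{n_bins}), \code{assay}, \code{organ},
#'   \code{replicate}, \code{n_transcripts}.
#' @export
metagene_profile <- function(lib, models, n_bins = 60, covered_only = FALSE) {
  covs <- .tx_coverage(lib, models)
  lens <- models$tx$tx_len
  keep <- lens >= n_bins
  acc <- numeric(n_bins)
  n_used <- 0L
  for (k in which(keep)) {
    v <- as.integer(covs[[k]])
    if (covered_only && !any(v > 0)) next
    L <- lens[k]
    bnd <- floor(L * (0:n_bins) / n_bins)
    cs <- c(0, cumsum(v))
    bin_cov <- cs[bnd[-1] + 1] - cs[bnd[-length(bnd)] + 1]
    width <- diff(bnd)
    acc <- acc + bin_cov / width * 1e3 * 1e6 / max(lib$total_mapped, 1L)
    n_used <- n_used + 1L
  }
  if (n_used == 0) stop("no transcript with usable length",
                        if (covered_only) "/coverage")
  structure(list(bins = acc / n_used, assay = lib$assay, organ = lib$organ,
                 replicate = lib$replicate, n_transcripts = n_used),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("metagene_profile: %s %s rep%d, %d bins over %d transcripts; argmax bin %d\n",
              x$organ, x$assay, x$replicate, length(x$bins),
              x$n_transcripts, which.max(x$bins) - 1L))
  invisible(x)
}

#' Compare metagene profiles across organs
#'
#' One-way ANOVA with bins as observations and profiles (organs) as groups;
#' a non-significant p indicates the overall topology is shared.
#'
#' @param profiles list of \code{\link{metagene_profile}} objects (>= 2) of
#'   equal length.
#' @return list with \code{p_value} and \code{f_statistic} (\code{p_value}
#'   is 1 with a \code{degenerate} flag when all values are identical).
#' @export
compare_profiles <- function(profiles) {
  if (length(profiles) < 2) stop("need at least 2 profiles")
  vals <- lapply(profiles, function(p)
    if (inherits(p, "metagene_profile")) p$bins else p)
  if (length(unique(lengths(vals))) != 1) stop("profiles of unequal length")
  v <- unlist(vals)
  g <- factor(rep(seq_along(vals), lengths(vals)))
  if (stats::var(v) == 0)
    return(list(p_value = 1, f_statistic = NA_real_, degenerate = TRUE))
  fit <- summary(stats::aov(v ~ g))[[1]]
  list(p_value = fit[["Pr(>F)"]][1], f_statistic = fit[["F value"]][1],
       degenerate = FALSE)
}

#' Extract coverage peaks per transcript
#'
#' Maximal runs of per-base depth >= \code{min_depth} in transcript
#' coordinates; the summit is the leftmost position of the run maximum.
#' At \code{min_depth = 1} the peak spans partition the covered bases, so
#' their total length equals \code{\link{covered_length}}.
#'
#' @param lib a \code{\link{fragment_library}}.
#' @param models a \code{\link{transcript_models}} object.
#' @param min_depth minimum depth (default 1).
#' @return data.frame: \code{transcript_id}, \code{start}, \code{end}
#'   (0-based half-open span), \code{summit} (0-based), \code{height}.
#' @export
call_peaks <- function(lib, models, min_depth = 1) {
  covs <- .tx_coverage(lib, models)
  views <- IRanges::slice(covs, lower = min_depth, rangesOnly = FALSE)
  n_per <- lengths(views)
  if (sum(n_per) == 0)
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), summit = integer(),
                      height = integer()))
  data.frame(
    transcript_id = rep(names(views), n_per),
    start = unlist(lapply(views, IRanges::start), use.names = FALSE) - 1L,
    end = unlist(lapply(views, IRanges::end), use.names = FALSE),
    summit = unlist(lapply(views, IRanges::viewWhichMaxs),
                    use.names = FALSE) - 1L,
    height = unlist(lapply(views, IRanges::viewMaxs), use.names = FALSE),
    stringsAsFactors = FALSE)
}

#' Classify m6A topology per transcript
#'
#' Type 1: the stop-codon region (stop codon - 100 nt to the transcript 3'
#' end) holds a peak at least \code{dominance_threshold} times the highest
#' peak of the upstream coding region (a stop-region peak with no coding
#' peak also counts). Type 2: no such dominance. Transcripts without a CDS
#' or without peaks are flagged not-applicable (\code{NA}).
#'
#' @param peaks output of \code{\link{call_peaks}}.
#' @param models a \code{\link{transcript_models}} object.
#' @param dominance_threshold stop/coding height ratio for Type 1
#'   (default 2).
#' @return data.frame: \code{transcript_id}, \code{type}
#'   (\code{"Type1"}/\code{"Type2"}/\code{NA}), \code{dominance_ratio}.
#' @export
classify_topology <- function(peaks, models, dominance_threshold = 2.0) {
  tx <- models$tx
  out <- data.frame(transcript_id = tx$transcript_id,
                    type = NA_character_, dominance_ratio = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(tx))) {
    if (is.na(tx$stop_pos[k])) next
    pk <- peaks[peaks$transcript_id == tx$transcript_id[k], ]
    if (nrow(pk) == 0) next
    stop_lo <- tx$stop_pos[k] - 100L
    in_stop <- pk$summit >= stop_lo
    in_cds <- pk$summit >= tx$cds_tx_start[k] & pk$summit < stop_lo
    stop_max <- if (any(in_stop)) max(pk$height[in_stop]) else 0
    cds_max <- if (any(in_cds)) max(pk$height[in_cds]) else 0
    ratio <- if (cds_max > 0) stop_max / cds_max else
      if (stop_max > 0) Inf else NA_real_
    out$dominance_ratio[k] <- ratio
    out$type[k] <- if (!is.na(ratio) && ratio >= dominance_threshold)
      "Type1" else "Type2"
  }
  out
}

#' RRACH consensus tally over top peaks
#'
#' Takes the \code{top_n} highest peaks, extracts \code{window} nt of
#' sense-strand transcript sequence centered on each summit (truncated at
#' transcript ends), and scans for the m6A consensus RRACH (R = A/G,
#' H = A/C/T in DNA space; the methylated A is position 3). A peak "has
#' consensus" when the window contains at least one match; per-5-mer
#' frequencies are tallied over the match nearest each summit (one instance
#' per peak) unless \code{per_peak = FALSE}, which counts every instance.
#'
#' @param peaks output of \code{\link{call_peaks}}.
#' @param genome named \code{DNAStringSet}.
#' @param models a \code{\link{transcript_models}} object.
#' @param top_n number of peaks to examine (default 1000).
#' @param window window length around the summit (default 100 nt).
#' @param per_peak one instance per peak (default) or all instances.
#' @return list: \code{n_peaks_examined}, \code{fraction_with_consensus}
#'   (\%), \code{motifs} data.frame (\code{motif}, \code{motif_rna} with U
#'   for T, \code{count}, \code{freq} \% over consensus instances).
#' @export
motif_table <- function(peaks, genome, models, top_n = 1000, window = 100,
                        per_peak = TRUE) {
  if (nrow(peaks) == 0) stop("no peaks")
  o <- order(-peaks$height, peaks$transcript_id, peaks$summit)
  pk <- peaks[o[seq_len(min(top_n, nrow(peaks)))], ]
  seqs <- transcript_sequences(genome, models)
  L <- stats::setNames(models$tx$tx_len, models$tx$transcript_id)
  ## a 2-nt margin so a 5-mer whose central A sits at the window edge is not
  ## clipped by the extraction
  ws <- pmax(pk$summit - window %/% 2L - 2L, 0L)
  we <- pmin(pk$summit + window %/% 2L + 2L, L[pk$transcript_id])
  win_seqs <- Biostrings::DNAStringSet(
    mapply(function(id, s, e) Biostrings::subseq(seqs[[id]], s + 1L, e),
           pk$transcript_id, ws, we))
  hits <- Biostrings::vmatchPattern("RRACH", win_seqs, fixed = FALSE)
  counts <- integer(0)
  n_with <- 0L
  inst <- character(0)
  for (i in seq_along(hits)) {
    h <- hits[[i]]
    if (length(h) == 0) next
    n_with <- n_with + 1L
    fivemers <- as.character(Biostrings::extractAt(win_seqs[[i]], h))
    if (per_peak) {
      summit_local <- pk$summit[i] - ws[i]
      d <- abs((IRanges::start(h) - 1L + 2L) - summit_local)
      fivemers <- fivemers[which.min(d)]
    }
    inst <- c(inst, fivemers)
  }
  tab <- sort(table(inst), decreasing = TRUE)
  motifs <- data.frame(motif = names(tab),
                       motif_rna = chartr("T", "U", names(tab)),
                       count = as.integer(tab),
                       freq = as.integer(tab) / sum(tab) * 100,
                       stringsAsFactors = FALSE)
  list(n_peaks_examined = nrow(pk),
       fraction_with_consensus = n_with / nrow(pk) * 100,
       motifs = motifs)
}
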