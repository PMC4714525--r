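#' Transcript model collection
#'
#' Container for exon-structured transcript models with CDS/UTR landmarks.
#' Genomic intervals are carried as 0-based half-open coordinates in the
#' exon table (the convention of BED and of all transcript-coordinate
#' quantities in this package); GFF3 1-based inclusive coordinates are
#' converted at the I/O boundary.
#'
#' @param tx data.frame with columns \code{transcript_id}, \code{chrom},
#'   \code{strand} (\code{"+"}/\code{"-"}), \code{biotype}, and optionally
#'   \code{cds_gstart}/\code{cds_gend} (genomic 0-based half-open CDS span,
#'   \code{NA} for non-coding).
#' @param exons data.frame with columns \code{transcript_id}, \code{start},
#'   \code{end} (genomic, 0-based half-open). Exons of one transcript must be
#'   non-overlapping.
#' @return An object of class \code{transcript_models}: the validated
#'   \code{tx} table gains \code{tx_len} (spliced length), \code{cds_tx_start},
#'   \code{cds_tx_end} (CDS in transcript coordinates) and \code{stop_pos}
#'   (0-based transcript coordinate of the last CDS base, i.e. the stop
#'   codon's 3' position).
#' @export
transcript_models <- function(tx, exons) {
  stopifnot(is.data.frame(tx), is.data.frame(exons))
  need <- c("transcript_id", "chrom", "strand", "biotype")
  if (!all(need %in% names(tx)))
    stop("tx must have columns: ", paste(need, collapse = ", "))
  if (!all(tx$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  exons <- exons[order(match(exons$transcript_id, tx$transcript_id), exons$start), ]
  if (any(exons$end <= exons$start))
    stop("exon with end <= start")
  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  if (!all(tx$transcript_id %in% names(sp)))
    stop("every transcript needs at least one exon")
  ## non-overlap check within transcript
  for (id in names(sp)) {
    i <- sp[[id]]
    if (length(i) > 1 && any(exons$start[i][-1] < exons$end[i][-length(i)]))
      stop("overlapping exons in transcript ", id)
  }
  wid <- exons$end - exons$start
  tx$tx_len <- as.integer(rowsum(wid, exons$transcript_id)[tx$transcript_id, 1])

  obj <- structure(list(tx = tx, exons = exons), class = "transcript_models")
  obj$exon_index <- .exon_index(obj)

  ## CDS landmarks in transcript coordinates
  tx$cds_tx_start <- NA_integer_
  tx$cds_tx_end <- NA_integer_
  tx$stop_pos <- NA_integer_
  if (!is.null(tx$cds_gstart)) {
    has <- !is.na(tx$cds_gstart)
    for (k in which(has)) {
      iv <- project_interval(tx$cds_gstart[k], tx$cds_gend[k],
                             tx$transcript_id[k], obj)
      if (is.null(iv))
        stop("cds_span outside exon union for ", tx$transcript_id[k])
      tx$cds_tx_start[k] <- iv[1]
      tx$cds_tx_end[k] <- iv[2]
      tx$stop_pos[k] <- iv[2] - 1L
    }
  }
  obj$tx <- tx
  obj
}

#' @export
print.transcript_models <- function(x, ...) {
  cat("transcript_models:", nrow(x$tx), "transcripts,",
      nrow(x$exons), "exons\n")
  invisible(x)
}

#' @export
length.transcript_models <- function(x) nrow(x$tx)

## Exon GRanges annotated with the transcript offset of each exon start in
## plus orientation; the workhorse index behind all projections.
.exon_index <- function(models) {
  ex <- models$exons
  tx <- models$tx
  m <- match(ex$transcript_id, tx$transcript_id)
  wid <- ex$end - ex$start
  off <- integer(nrow(ex))
  prev <- ""
  acc <- 0L
  for (i in seq_len(nrow(ex))) {
    if (ex$transcript_id[i] != prev) { acc <- 0L; prev <- ex$transcript_id[i] }
    off[i] <- acc
    acc <- acc + wid[i]
  }
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = "*")
  S4Vectors::mcols(gr)$tx_id <- ex$transcript_id
  S4Vectors::mcols(gr)$off <- off
  S4Vectors::mcols(gr)$tx_len <- tx$tx_len[m]
  S4Vectors::mcols(gr)$tx_strand <- tx$strand[m]
  gr
}

#' Project a genomic interval onto one transcript
#'
#' Maps a genomic 0-based half-open interval onto spliced transcript
#' coordinates (0-based half-open, 0 = transcript 5' end; reverse-strand
#' transcripts are flipped accordingly). Only the exon-overlapping part is
#' mapped; intronic overhang is discarded.
#'
#' @param gstart,gend genomic interval, 0-based half-open.
#' @param transcript_id transcript to project onto.
#' @param models a \code{\link{transcript_models}} object.
#' @return Integer vector \code{c(start, end)} in transcript coordinates, or
#'   \code{NULL} when the interval does not overlap the transcript's exons.
#' @export
project_interval <- function(gstart, gend, transcript_id, models) {
  idx <- models$exon_index
  keep <- S4Vectors::mcols(idx)$tx_id == transcript_id
  ex <- idx[keep]
  if (length(ex) == 0) return(NULL)
  is <- pmax(gstart, GenomicRanges::start(ex) - 1L)
  ie <- pmin(gend, GenomicRanges::end(ex))
  hit <- ie > is
  if (!any(hit)) return(NULL)
  off <- S4Vectors::mcols(ex)$off[hit]
  ps <- off + (is[hit] - (GenomicRanges::start(ex)[hit] - 1L))
  pe <- ps + (ie[hit] - is[hit])
  L <- S4Vectors::mcols(ex)$tx_len[1]
  if (S4Vectors::mcols(ex)$tx_strand[1] == "-") {
    out <- c(L - max(pe), L - min(ps))
  } else {
    out <- c(min(ps), max(pe))
  }
  as.integer(out)
}

#' Project fragments onto all overlapping transcripts
#'
#' Every (fragment, transcript) exon-overlap pair yields one projected
#' interval in spliced transcript coordinates; a fragment overlapping several
#' transcripts is counted for each. Fragments with no exon overlap are
#' dropped here but still count toward library totals.
#'
#' @param fragments a \code{GRanges} of fragment alignments (as in a
#'   \code{\link{fragment_library}}) or a data.frame with \code{chrom},
#'   \code{start}, \code{end} (0-based half-open).
#' @param models a \code{\link{transcript_models}} object.
#' @return data.frame with columns \code{fragment} (index into the input),
#'   \code{transcript_id}, \code{start}, \code{end} (transcript coordinates,
#'   0-based half-open).
#' @export
project_fragments <- function(fragments, models) {
  if (is.data.frame(fragments)) {
    fragments <- GenomicRanges::GRanges(
      fragments$chrom,
      IRanges::IRanges(fragments$start + 1L, fragments$end))
  }
  idx <- models$exon_index
  hits <- GenomicRanges::findOverlaps(fragments, idx, ignore.strand = TRUE)
  if (length(hits) == 0)
    return(data.frame(fragment = integer(), transcript_id = character(),
                      start = integer(), end = integer()))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  is <- pmax(GenomicRanges::start(fragments)[q], GenomicRanges::start(idx)[s])
  ie <- pmin(GenomicRanges::end(fragments)[q], GenomicRanges::end(idx)[s])
  off <- S4Vectors::mcols(idx)$off[s]
  ps <- off + (is - GenomicRanges::start(idx)[s])          # 0-based plus-strand
  pe <- ps + (ie - is + 1L)
  L <- S4Vectors::mcols(idx)$tx_len[s]
  neg <- S4Vectors::mcols(idx)$tx_strand[s] == "-"
  ts <- ifelse(neg, L - pe, ps)
  te <- ifelse(neg, L - ps, pe)
  txid <- S4Vectors::mcols(idx)$tx_id[s]

  ## merge pieces of one fragment on one transcript (they are contiguous in
  ## transcript coordinates because the intron between them is spliced out)
  key <- paste0(q, "\r", txid)
  if (anyDuplicated(key)) {
    o <- order(key, ts)
    first <- !duplicated(key[o])
    o2 <- order(key, -te)
    first2 <- !duplicated(key[o2])
    data.frame(fragment = q[o][first],
               transcript_id = txid[o][first],
               start = as.integer(ts[o][first]),
               end = as.integer(te[o2][first2]))
  } else {
    data.frame(fragment = q, transcript_id = txid,
               start = as.integer(ts), end = as.integer(te))
  }
}

## inverse map: transcript interval -> genomic span (single interval; a
## fragment crossing an intron is reported as its genomic span, the way a
## spliced alignment occupies the genome)
.tx_to_genomic <- function(models, transcript_id, ts, te) {
  tx <- models$tx
  k <- match(transcript_id, tx$transcript_id)
  ex <- models$exons[models$exons$transcript_id == tx$transcript_id[k], ]
  wid <- ex$end - ex$start
  off <- cumsum(c(0L, wid[-length(wid)]))
  L <- tx$tx_len[k]
  if (tx$strand[k] == "-") { p1 <- L - te; p2 <- L - ts } else { p1 <- ts; p2 <- te }
  gpos <- function(p) { # plus-orientation transcript coord -> genomic coord
    i <- findInterval(p, off)
    ex$start[i] + (p - off[i])
  }
  g1 <- gpos(p1)
  g2 <- gpos(p2 - 1L) + 1L
  c(g1, g2)
}

#' Extract spliced transcript sequences
#'
#' @param genome a named \code{DNAStringSet} (one entry per chromosome).
#' @param models a \code{\link{transcript_models}} object.
#' @return \code{DNAStringSet} of sense-strand transcript sequences, named by
#'   transcript id (reverse-strand transcripts are reverse-complemented).
#' @export
transcript_sequences <- function(genome, models) {
  tx <- models$tx
  out <- vector("list", nrow(tx))
  for (k in seq_len(nrow(tx))) {
    ex <- models$exons[models$exons$transcript_id == tx$transcript_id[k], ]
    seqs <- Biostrings::DNAStringSet(genome[[tx$chrom[k]]],
                                     start = ex$start + 1L, end = ex$end)
    s <- Biostrings::DNAString(paste(as.character(seqs), collapse = ""))
    if (tx$strand[k] == "-") s <- Biostrings::reverseComplement(s)
    out[[k]] <- s
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- tx$transcript_id
  res
}
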