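## Readers/writers for the standard formats the pipeline touches. Parsing of
## GFF3/BED/bedGraph/FASTA is delegated to rtracklayer/Biostrings; this file
## only adapts their containers to the package's transcript model.

.BIOTYPE_MAP <- c(
  mRNA = "mRNA", transcript = "mRNA",
  rRNA = "rRNA", tRNA = "tRNA", snRNA = "snRNA", snoRNA = "snoRNA",
  transposable_element = "TE", transposable_element_gene = "TE",
  transposon_fragment = "TE",
  pseudogene = "pseudogene", pseudogenic_transcript = "pseudogene",
  ncRNA = "other_ncRNA", lnc_RNA = "other_ncRNA", miRNA = "other_ncRNA",
  antisense_RNA = "other_ncRNA")

#' Read transcript models from a GFF3 annotation
#'
#' Transcript-level features (mRNA, rRNA, tRNA, sn/snoRNA, pseudogene, TE,
#' ncRNA, ...) are collected together with their child exon and CDS features
#' (linked by \code{Parent}). GFF3's 1-based inclusive coordinates are
#' converted to the package's 0-based half-open convention at this boundary.
#' A transcript feature without exon children is treated as a single exon
#' spanning the feature.
#'
#' @param path GFF3 file.
#' @return A \code{\link{transcript_models}} object. Biotype defaults to
#'   \code{"mRNA"} for unrecognized feature types.
#' @export
read_annotation <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("GFF3 parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  type <- as.character(S4Vectors::mcols(gr)$type)
  id <- as.character(S4Vectors::mcols(gr)$ID)
  parent <- S4Vectors::mcols(gr)$Parent
  parent1 <- vapply(as.list(parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))

  exon_rows <- which(type == "exon")
  cds_rows <- which(type == "CDS")
  is_txtype <- type %in% names(.BIOTYPE_MAP)
  referenced <- unique(parent1[exon_rows])
  is_tx <- is_txtype | (!is.na(id) & id %in% referenced & type != "gene")
  tx_rows <- which(is_tx)
  if (length(tx_rows) == 0)
    stop("no transcript features found in ", path)

  tx <- data.frame(
    transcript_id = ifelse(is.na(id[tx_rows]),
                           paste0("tx", seq_along(tx_rows)), id[tx_rows]),
    chrom = as.character(GenomicRanges::seqnames(gr))[tx_rows],
    strand = as.character(GenomicRanges::strand(gr))[tx_rows],
    biotype = unname(ifelse(type[tx_rows] %in% names(.BIOTYPE_MAP),
                            .BIOTYPE_MAP[type[tx_rows]], "mRNA")),
    stringsAsFactors = FALSE)
  if (any(!tx$strand %in% c("+", "-")))
    stop("transcript feature without strand in ", path)
  tx_start <- GenomicRanges::start(gr)[tx_rows] - 1L
  tx_end <- GenomicRanges::end(gr)[tx_rows]

  ex_parent <- parent1[exon_rows]
  keep <- ex_parent %in% tx$transcript_id
  exons <- data.frame(
    transcript_id = ex_parent[keep],
    chrom = as.character(GenomicRanges::seqnames(gr))[exon_rows][keep],
    start = GenomicRanges::start(gr)[exon_rows][keep] - 1L,
    end = GenomicRanges::end(gr)[exon_rows][keep],
    stringsAsFactors = FALSE)
  ## transcripts without exon children: the feature span is the single exon
  missing <- setdiff(tx$transcript_id, exons$transcript_id)
  if (length(missing)) {
    m <- match(missing, tx$transcript_id)
    exons <- rbind(exons, data.frame(
      transcript_id = missing, chrom = tx$chrom[m],
      start = tx_start[m], end = tx_end[m], stringsAsFactors = FALSE))
  }
  ## validate exons against the declared transcript span
  m <- match(exons$transcript_id, tx$transcript_id)
  bad <- exons$start < tx_start[m] | exons$end > tx_end[m]
  if (any(bad))
    stop("exon outside declared transcript span: ",
         paste(unique(exons$transcript_id[bad]), collapse = ", "))

  if (length(cds_rows)) {
    cp <- parent1[cds_rows]
    keep <- cp %in% tx$transcript_id
    if (any(keep)) {
      csplit <- split(which(keep), cp[keep])
      tx$cds_gstart <- NA_integer_
      tx$cds_gend <- NA_integer_
      for (idc in names(csplit)) {
        i <- cds_rows[csplit[[idc]]]
        k <- match(idc, tx$transcript_id)
        tx$cds_gstart[k] <- min(GenomicRanges::start(gr)[i]) - 1L
        tx$cds_gend[k] <- max(GenomicRanges::end(gr)[i])
      }
    }
  }
  transcript_models(tx, exons)
}

#' Write transcript models to GFF3
#'
#' @param models a \code{\link{transcript_models}} object.
#' @param path output file.
#' @export
write_annotation <- function(models, path) {
  tx <- models$tx
  ex <- models$exons
  type_map <- c(mRNA = "mRNA", rRNA = "rRNA", tRNA = "tRNA", snRNA = "snRNA",
                snoRNA = "snoRNA", TE = "transposable_element_gene",
                pseudogene = "pseudogene", other_ncRNA = "ncRNA")
  tx_span_start <- vapply(tx$transcript_id, function(id)
    as.integer(min(ex$start[ex$transcript_id == id])), integer(1))
  tx_span_end <- vapply(tx$transcript_id, function(id)
    as.integer(max(ex$end[ex$transcript_id == id])), integer(1))
  rows <- list()
  rows$tx <- GenomicRanges::GRanges(
    tx$chrom, IRanges::IRanges(tx_span_start + 1L, tx_span_end),
    strand = tx$strand,
    type = unname(type_map[tx$biotype]),
    ID = tx$transcript_id, Parent = NA_character_, phase = NA_integer_)
  m <- match(ex$transcript_id, tx$transcript_id)
  rows$exon <- GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end),
    strand = tx$strand[m], type = "exon",
    ID = NA_character_, Parent = ex$transcript_id, phase = NA_integer_)
  has_cds <- !is.null(tx$cds_gstart) && any(!is.na(tx$cds_gstart))
  if (has_cds) {
    k <- which(!is.na(tx$cds_gstart))
    rows$cds <- GenomicRanges::GRanges(
      tx$chrom[k], IRanges::IRanges(tx$cds_gstart[k] + 1L, tx$cds_gend[k]),
      strand = tx$strand[k], type = "CDS",
      ID = NA_character_, Parent = tx$transcript_id[k], phase = 0L)
  }
  all <- suppressWarnings(do.call(c, unname(rows)))
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Fragment library
#'
#' Deduplicated fragment alignments for one \{organ, replicate, assay\}
#' library, plus the library-wide mapped total used by the per-million terms
#' of FPKM/MFPKM.
#'
#' @param fragments \code{GRanges} of fragment intervals.
#' @param organ free organ/tissue label (e.g. \code{"leaves"}).
#' @param replicate integer replicate number (>= 1).
#' @param assay one of \code{"m6A"}, \code{"mRNA"}, \code{"input"}.
#' @param total_mapped library total; defaults to the number of fragments.
#' @export
fragment_library <- function(fragments, organ, replicate, assay,
                             total_mapped = length(fragments)) {
  assay <- match.arg(assay, c("m6A", "mRNA", "input"))
  stopifnot(methods::is(fragments, "GRanges"),
            is.numeric(replicate), replicate >= 1, total_mapped >= 0)
  structure(list(fragments = fragments, organ = organ,
                 replicate = as.integer(replicate), assay = assay,
                 total_mapped = as.integer(total_mapped)),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat(sprintf("fragment_library: %s rep%d %s, %d fragments (total_mapped %d)\n",
              x$organ, x$replicate, x$assay, length(x$fragments),
              x$total_mapped))
  invisible(x)
}

#' Read a fragment library from BED
#'
#' @param path BED3+ file (0-based half-open).
#' @inheritParams fragment_library
#' @return a \code{\link{fragment_library}} with
#'   \code{total_mapped = } record count.
#' @export
read_fragments <- function(path, organ, replicate, assay) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) stop("BED validation error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(gr) && any(GenomicRanges::width(gr) < 1))
    stop("BED validation error in '", path, "': interval with end <= start")
  fragment_library(gr, organ, replicate, assay)
}

#' Write a fragment library to BED
#' @param lib a \code{\link{fragment_library}}.
#' @param path output file.
#' @export
write_fragments <- function(lib, path) {
  gr <- GenomicRanges::sort(lib$fragments, ignore.strand = TRUE)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write per-base coverage to bedGraph
#'
#' Depth is the count of overlapping fragments; zero-depth runs are omitted.
#' Output is 0-based half-open (bedGraph convention) and ordered by
#' chromosome and start.
#'
#' @param lib a \code{\link{fragment_library}} (or a \code{GRanges}).
#' @param path output bedGraph file.
#' @export
write_coverage <- function(lib, path) {
  gr <- if (methods::is(lib, "GRanges")) lib else lib$fragments
  cov <- GenomicRanges::coverage(gr)
  covgr <- GenomicRanges::GRanges(cov)
  covgr <- covgr[S4Vectors::mcols(covgr)$score > 0]
  covgr <- GenomicRanges::sort(covgr)
  rtracklayer::export(covgr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph coverage track
#' @param path bedGraph file.
#' @return \code{GRanges} with a \code{score} (depth) column.
#' @export
read_coverage <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' Write / read tabular records as TSV
#'
#' Plain TSV with a header row; rows are ordered by \code{transcript_id}
#' when that column is present, so output is deterministic.
#'
#' @param records a data.frame.
#' @param path file path.
#' @export
write_table <- function(records, path) {
  if ("transcript_id" %in% names(records))
    records <- records[order(records$transcript_id), , drop = FALSE]
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a genome to FASTA
#' @param genome named \code{DNAStringSet}.
#' @param path output FASTA file.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file.
#' @return named \code{DNAStringSet}.
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}
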