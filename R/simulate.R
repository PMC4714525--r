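## Synthetic m6A-seq/mRNA-seq/input data with known ground truth.
##
## The generator lays out non-overlapping transcripts on a small multi-
## chromosome genome of random bases, plants an RRACH 5-mer at every true
## m6A site, and simulates fragmentation (~100 nt) plus antibody capture
## (per-fragment Bernoulli; non-specific rate < 1%). Everything is seeded.

.RRACH <- as.vector(outer(outer(c("A", "G"), c("A", "G"), paste0),
                          paste0("AC", c("A", "C", "T")), paste0))

.default_motif_weights <- function() {
  w <- stats::setNames(rep((1 - 0.193 - 0.190) / 10, 12), .RRACH)
  w["AAACT"] <- 0.193   # AAm6ACU, the most frequent consensus instance
  w["AAACA"] <- 0.190
  w
}

#' Simulation parameters
#'
#' Defaults define the desk-scale study conditions: 500 transcripts across 5
#' chromosomes, 3 organs x 2 replicates, 2e5 fragments per library, ~100-nt
#' fragments, < 1\% non-specific capture, >= 70\% of m6A sites anchored at the
#' stop codon/3'UTR, and a 10\% subset of methylated transcripts planted with
#' a 4-fold between-organ methylation difference.
#'
#' @param n_transcripts number of transcripts.
#' @param organs organ labels.
#' @param replicates replicates per organ.
#' @param utr5_range,utr3_range uniform ranges (nt) for the UTR lengths.
#' @param cds_codons uniform range for CDS length in codons.
#' @param expr_meanlog,expr_sdlog log-normal expression weights (the weight is
#'   a transcript's expected share of the fragmented RNA pool).
#' @param frac_methylated fraction of transcripts carrying true m6A sites.
#' @param sites_per_tx named probability vector over site counts per
#'   methylated transcript.
#' @param placement probability mass over site regions
#'   \code{c(stop=, cds=, five=)}; the stop mass is also the fraction of
#'   transcripts with Type 1 (stop-codon dominant) topology.
#' @param min_site_gap preferred minimum spacing between sites (nt).
#' @param fragment_mean,fragment_sd,fragment_min fragment length model (nt);
#'   lengths are truncated at \code{fragment_min}.
#' @param p_specific capture probability for a fragment covering a true site
#'   (scaled by the transcript/organ methylation level).
#' @param p_nonspecific capture probability for any other fragment; the
#'   default 5e-4 puts roughly 1\% non-site fragments into a captured
#'   library, matching the reported < 1\% non-specific immunoprecipitation.
#' @param meth_base methylation level of a typical methylated transcript.
#' @param frac_extreme fraction of methylated transcripts planted at full
#'   methylation level 1 (the "extensively methylated" truth set).
#' @param dm_fraction fraction of methylated transcripts planted with a
#'   between-organ methylation difference (focal organs alternate so library
#'   totals stay balanced).
#' @param dm_fold planted fold difference in methylation level.
#' @param te_fraction fraction of transcripts that are TE ("fragmented")
#'   transcripts, sampled only within 2-4 disjoint sub-intervals.
#' @param two_exon_fraction fraction of transcripts given two exons.
#' @param intron_len intron length (nt) for two-exon transcripts.
#' @param depth fragments per library.
#' @param n_chrom chromosomes.
#' @param gap intergenic gap (nt).
#' @param motif_weights named probability vector over the 12 RRACH 5-mers
#'   planted at sites.
#' @param seed integer seed; all outputs are reproducible given the seed.
#' @return a list of parameters (class \code{sim_params}).
#' @export
sim_params <- function(n_transcripts = 500,
                       organs = c("leaves", "flowers", "roots"),
                       replicates = 2,
                       utr5_range = c(50, 200),
                       cds_codons = c(150, 450),
                       utr3_range = c(150, 300),
                       expr_meanlog = 0, expr_sdlog = 1,
                       frac_methylated = 0.75,
                       sites_per_tx = c(`1` = 0.35, `2` = 0.35,
                                        `3` = 0.20, `4` = 0.10),
                       placement = c(stop = 0.75, cds = 0.20, five = 0.05),
                       min_site_gap = 200,
                       fragment_mean = 100, fragment_sd = 20,
                       fragment_min = 30,
                       p_specific = 0.9, p_nonspecific = 5e-4,
                       meth_base = 0.35, frac_extreme = 0.06,
                       dm_fraction = 0.10, dm_fold = 4,
                       te_fraction = 0.03,
                       two_exon_fraction = 0.2, intron_len = 150,
                       depth = 2e5, n_chrom = 5, gap = 300,
                       motif_weights = .default_motif_weights(),
                       seed = 1) {
  p <- as.list(environment())
  stopifnot(p$n_transcripts >= 1, p$depth > 0,
            all(p$placement >= 0), abs(sum(p$placement) - 1) < 1e-8,
            p$p_specific >= 0, p$p_specific <= 1,
            p$p_nonspecific >= 0, p$p_nonspecific < p$p_specific,
            p$frac_methylated >= 0, p$frac_methylated <= 1,
            abs(sum(p$motif_weights) - 1) < 1e-8,
            all(names(p$motif_weights) %in% .RRACH))
  structure(p, class = "sim_params")
}

.rand_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

## place n sites inside windows (list of c(from, to), 0-based, to exclusive
## for the A position), respecting a preferred minimum gap
.place_sites <- function(windows, n, gap) {
  widths <- vapply(windows, function(w) max(0L, w[2] - w[1]), numeric(1))
  if (all(widths <= 0) || n == 0) return(integer(0))
  ## never closer than the 5-mer itself, so planted motifs cannot collide
  gap_eff <- max(5L, min(gap, floor(sum(widths) / max(1, n))))
  pos <- integer(0)
  for (i in seq_len(n)) {
    cand <- NA_integer_
    for (try in 1:100) {
      w <- windows[[sample.int(length(windows), 1, prob = widths + 1e-9)]]
      if (w[2] <= w[1]) next
      cand <- w[1] + sample.int(w[2] - w[1], 1) - 1L
      if (!length(pos) || min(abs(pos - cand)) >= gap_eff) break
    }
    if (!is.na(cand) && (!length(pos) || min(abs(pos - cand)) >= 5))
      pos <- c(pos, cand)
  }
  sort(unique(pos))
}

#' Generate a synthetic reference with ground truth
#'
#' @param params a \code{\link{sim_params}} object.
#' @return list with \code{genome} (\code{DNAStringSet}), \code{models}
#'   (\code{\link{transcript_models}}) and \code{truth}, a list of
#'   data.frames: \code{transcripts} (biotype, methylation design, topology
#'   type, expression weight, focal organ of any planted differential
#'   methylation), \code{meth_levels} (transcript x organ methylation level),
#'   \code{sites} (0-based transcript coordinate of each m6A site and its
#'   planted RRACH 5-mer) and \code{te_windows} (sub-intervals to which TE
#'   transcript sampling is restricted).
#' @export
generate_reference <- function(params = sim_params()) {
  set.seed(params$seed)
  ntx <- params$n_transcripts
  organs <- params$organs

  utr5 <- sample(params$utr5_range[1]:params$utr5_range[2], ntx, TRUE)
  cds <- 3L * sample(params$cds_codons[1]:params$cds_codons[2], ntx, TRUE)
  utr3 <- sample(params$utr3_range[1]:params$utr3_range[2], ntx, TRUE)
  len <- utr5 + cds + utr3
  chrom_i <- ((seq_len(ntx) - 1L) %% params$n_chrom) + 1L
  counter <- stats::ave(seq_len(ntx), chrom_i, FUN = seq_along)
  ids <- sprintf("AT%dG%05d", chrom_i, 10L * counter)
  strand <- rep(c("+", "-"), length.out = ntx)
  biotype <- ifelse(stats::runif(ntx) < params$te_fraction, "TE", "mRNA")
  two_exon <- stats::runif(ntx) < params$two_exon_fraction
  junction <- ifelse(two_exon,
                     floor(len / 3) + floor(stats::runif(ntx) * len / 3), NA)

  methylated <- stats::runif(ntx) < params$frac_methylated
  extent_group <- ifelse(!methylated, "unmethylated",
                         ifelse(stats::runif(ntx) < params$frac_extreme,
                                "extreme", "typical"))
  n_sites <- ifelse(!methylated, 0L,
                    ifelse(extent_group == "extreme", 2L,
                           as.integer(sample(as.integer(names(params$sites_per_tx)),
                                             ntx, TRUE,
                                             prob = params$sites_per_tx))))
  has_cds <- biotype == "mRNA"
  topology <- rep(NA_character_, ntx)
  topology[has_cds & methylated] <-
    ifelse(stats::runif(sum(has_cds & methylated)) <
             unname(params$placement["stop"]), "Type1", "Type2")

  expr_weight <- stats::rlnorm(ntx, params$expr_meanlog, params$expr_sdlog)

  ## differential methylation design: focal organs alternate
  dm_focal <- rep(NA_character_, ntx)
  if (params$dm_fraction > 0 && length(organs) >= 2) {
    cand <- which(methylated)
    ndm <- round(params$dm_fraction * length(cand))
    pick <- sample(cand, ndm)
    dm_focal[pick] <- rep_len(organs, ndm)
  }
  base_level <- ifelse(!methylated, 0,
                       ifelse(extent_group == "extreme", 1, params$meth_base))
  meth <- matrix(base_level, nrow = ntx, ncol = length(organs),
                 dimnames = list(ids, organs))
  for (k in which(!is.na(dm_focal))) {
    others <- setdiff(organs, dm_focal[k])
    meth[k, others] <- meth[k, others] / params$dm_fold
  }

  ## site placement
  stop_pos <- ifelse(has_cds, utr5 + cds - 1L, NA)
  sites_list <- vector("list", ntx)
  for (k in seq_len(ntx)) {
    ns <- n_sites[k]
    if (ns == 0) { sites_list[[k]] <- integer(0); next }
    if (!has_cds[k]) {
      win <- list(c(2L, len[k] - 3L))
    } else if (!is.na(topology[k]) && topology[k] == "Type1") {
      win <- list(c(max(2L, stop_pos[k] - 100L), len[k] - 3L))
    } else {
      pc <- params$placement[c("cds", "five")]
      if (sum(pc) <= 0) pc <- c(cds = 1, five = 0)
      cds_win <- c(max(2L, utr5[k] + 3L), max(2L, stop_pos[k] - 110L))
      five_win <- c(2L, utr5[k])
      win <- lapply(seq_len(ns), function(i) {
        reg <- sample(c("cds", "five"), 1, prob = pc)
        if (reg == "five" && five_win[2] > five_win[1]) five_win else cds_win
      })
      widths <- vapply(win, function(w) max(0, w[2] - w[1]), numeric(1))
      gap_eff <- max(5L, min(params$min_site_gap,
                             floor(sum(widths) / max(1, ns))))
      pos <- integer(0)
      for (i in seq_len(ns)) {
        w <- win[[i]]
        if (w[2] <= w[1]) next
        for (try in 1:100) {
          cand <- w[1] + sample.int(w[2] - w[1], 1) - 1L
          if (!length(pos) || min(abs(pos - cand)) >= gap_eff) {
            pos <- c(pos, cand)
            break
          }
        }
      }
      pos <- sort(unique(pos))
      ## keep sites clear of the exon junction so the 5-mer is not split
      if (two_exon[k])
        pos <- pos[abs(pos - junction[k]) > 5]
      sites_list[[k]] <- pos
      next
    }
    pos <- .place_sites(win, ns, params$min_site_gap)
    if (two_exon[k]) pos <- pos[abs(pos - junction[k]) > 5]
    sites_list[[k]] <- pos
  }
  n_sites <- lengths(sites_list)
  methylated <- n_sites > 0
  extent_group[!methylated] <- "unmethylated"
  meth[!methylated, ] <- 0
  dm_focal[!methylated] <- NA

  motifs_list <- lapply(sites_list, function(p)
    sample(names(params$motif_weights), length(p), TRUE,
           prob = params$motif_weights))

  ## TE sampling windows (2-4 disjoint sub-intervals)
  te_rows <- list()
  for (k in which(biotype == "TE")) {
    nw <- sample(2:4, 1)
    bnd <- sort(sample(seq(50L, len[k] - 50L), 2L * nw))
    te_rows[[length(te_rows) + 1]] <- data.frame(
      transcript_id = ids[k],
      start = bnd[seq(1, 2 * nw, 2)], end = bnd[seq(2, 2 * nw, 2)])
  }
  te_windows <- if (length(te_rows)) do.call(rbind, te_rows) else
    data.frame(transcript_id = character(), start = integer(),
               end = integer())

  ## genome assembly
  il <- params$intron_len
  glen <- len + ifelse(two_exon, il, 0L)
  gstart <- integer(ntx)
  chrom_seqs <- vector("list", params$n_chrom)
  cursor <- integer(params$n_chrom)
  exon_rows <- vector("list", ntx)
  cds_g <- matrix(NA_integer_, ntx, 2)
  for (k in seq_len(ntx)) {
    ci <- chrom_i[k]
    gs <- cursor[ci] + params$gap
    gstart[k] <- gs
    txseq <- .rand_bases(len[k])
    for (i in seq_along(sites_list[[k]])) {
      p <- sites_list[[k]][i]
      txseq[(p - 1L):(p + 3L)] <- strsplit(motifs_list[[k]][i], "")[[1]]
    }
    j <- junction[k]
    unspliced <- if (two_exon[k])
      c(txseq[seq_len(j)], .rand_bases(il), txseq[(j + 1L):len[k]])
    else txseq
    plus_seq <- if (strand[k] == "-")
      rev(chartr("ACGT", "TGCA", unspliced)) else unspliced
    chrom_seqs[[ci]] <- c(chrom_seqs[[ci]], .rand_bases(params$gap), plus_seq)
    cursor[ci] <- gs + glen[k]

    if (two_exon[k]) {
      if (strand[k] == "+") {
        exon_rows[[k]] <- data.frame(
          transcript_id = ids[k], chrom = paste0("Chr", ci),
          start = c(gs, gs + j + il), end = c(gs + j, gs + glen[k]))
      } else {
        exon_rows[[k]] <- data.frame(
          transcript_id = ids[k], chrom = paste0("Chr", ci),
          start = c(gs, gs + (len[k] - j) + il),
          end = c(gs + (len[k] - j), gs + glen[k]))
      }
    } else {
      exon_rows[[k]] <- data.frame(
        transcript_id = ids[k], chrom = paste0("Chr", ci),
        start = gs, end = gs + glen[k])
    }
    if (has_cds[k]) {
      ## genomic span of the CDS through the (possibly intron-split) layout
      u <- function(p) p + ifelse(two_exon[k] & p >= j, il, 0L)
      p1 <- utr5[k]; p2 <- utr5[k] + cds[k] - 1L
      if (strand[k] == "+") {
        cds_g[k, ] <- c(gs + u(p1), gs + u(p2) + 1L)
      } else {
        pp1 <- len[k] - 1L - p2; pp2 <- len[k] - 1L - p1
        jj <- len[k] - j
        u2 <- function(p) p + ifelse(two_exon[k] & p >= jj, il, 0L)
        cds_g[k, ] <- c(gs + u2(pp1), gs + u2(pp2) + 1L)
      }
    }
  }
  genome <- Biostrings::DNAStringSet(vapply(seq_len(params$n_chrom),
    function(ci) paste(c(chrom_seqs[[ci]], .rand_bases(params$gap)),
                       collapse = ""), character(1)))
  names(genome) <- paste0("Chr", seq_len(params$n_chrom))

  tx <- data.frame(transcript_id = ids, chrom = paste0("Chr", chrom_i),
                   strand = strand, biotype = biotype,
                   cds_gstart = cds_g[, 1], cds_gend = cds_g[, 2],
                   stringsAsFactors = FALSE)
  models <- transcript_models(tx, do.call(rbind, exon_rows))

  sites <- data.frame(
    transcript_id = rep(ids, n_sites),
    pos = unlist(sites_list),
    motif = unlist(motifs_list))
  truth <- list(
    transcripts = data.frame(
      transcript_id = ids, biotype = biotype, methylated = methylated,
      extent_group = extent_group, n_sites = n_sites, topology = topology,
      dm_focal = dm_focal, expr_weight = expr_weight,
      stringsAsFactors = FALSE),
    meth_levels = data.frame(
      transcript_id = rep(ids, length(organs)),
      organ = rep(organs, each = ntx),
      meth_level = as.vector(meth)),
    sites = sites,
    te_windows = te_windows)
  list(genome = genome, models = models, truth = truth)
}

## vectorized draw of n fragments in transcript coordinates; start positions
## use a clip model (uniform over [-(len-1), L-1], clipped to the transcript)
## so steady-state coverage is uniform along the transcript
.draw_fragments <- function(n, params, L, w, te_idx, te_win) {
  ti <- sample.int(length(L), n, TRUE, prob = w)
  fl <- pmin(pmax(round(stats::rnorm(n, params$fragment_mean,
                                     params$fragment_sd)),
                  params$fragment_min), 3L * params$fragment_mean)
  fl <- pmin(fl, L[ti])
  lo <- -(fl - 1L)
  hi <- L[ti]
  is_te <- ti %in% te_idx
  if (any(is_te)) {
    ii <- which(is_te)
    wrow <- vapply(ii, function(i) {
      rows <- which(te_win$tx == ti[i])
      rows[sample.int(length(rows), 1,
                      prob = te_win$end[rows] - te_win$start[rows])]
    }, integer(1))
    lo[ii] <- te_win$start[wrow] - (fl[ii] - 1L)
    hi[ii] <- te_win$end[wrow]
    wlo <- te_win$start[wrow]; whi <- te_win$end[wrow]
  }
  s0 <- floor(stats::runif(n, lo, hi))
  fs <- pmax(s0, 0L)
  fe <- pmin(s0 + fl, L[ti])
  if (any(is_te)) {
    ii <- which(is_te)
    fs[ii] <- pmax(s0[ii], wlo)
    fe[ii] <- pmin(s0[ii] + fl[ii], whi)
  }
  list(ti = ti, fs = as.integer(fs), fe = as.integer(fe))
}

#' Simulate fragment libraries from a synthetic reference
#'
#' mRNA-seq and input fragments are drawn proportional to expression weights,
#' uniformly along each transcript; m6A-seq fragments are retained with
#' probability \code{p_specific * meth_level} when they cover a true site and
#' \code{p_nonspecific} otherwise, until the requested depth is reached.
#'
#' @param reference output of \code{\link{generate_reference}}.
#' @param params the \code{\link{sim_params}} used to build the reference.
#' @param assays which assays to simulate.
#' @param organs,replicates subset of the parameter grid to simulate
#'   (\code{replicates} is a vector of replicate indices).
#' @param depth fragments per library.
#' @return named list of \code{\link{fragment_library}} objects
#'   (\code{"<organ>_rep<r>_<assay>"}).
#' @export
simulate_libraries <- function(reference, params,
                               assays = c("m6A", "mRNA", "input"),
                               organs = params$organs,
                               replicates = seq_len(params$replicates),
                               depth = params$depth) {
  if (depth <= 0) stop("zero-depth request")
  assays <- match.arg(assays, c("m6A", "mRNA", "input"), several.ok = TRUE)
  models <- reference$models
  truth <- reference$truth
  ids <- models$tx$transcript_id
  L <- models$tx$tx_len
  ntx <- length(ids)
  w <- truth$transcripts$expr_weight
  te_idx <- which(truth$transcripts$biotype == "TE")
  te_win <- truth$te_windows
  te_win$tx <- match(te_win$transcript_id, ids)
  meth <- matrix(truth$meth_levels$meth_level, nrow = ntx,
                 dimnames = list(ids, unique(truth$meth_levels$organ)))
  A <- cumsum(c(0, L + 1))          # absolute offsets, 1 spacer between tx
  site_abs <- IRanges::IRanges(
    start = A[match(truth$sites$transcript_id, ids)] + truth$sites$pos + 1L,
    width = 1L)

  ## one seed per cell of the full parameter grid, so a library's stream does
  ## not depend on which subset was requested
  set.seed(params$seed)
  grid <- expand.grid(assay = c("m6A", "mRNA", "input"),
                      replicate = seq_len(params$replicates),
                      organ = params$organs, stringsAsFactors = FALSE)
  grid$seed <- sample.int(.Machine$integer.max - 1L, nrow(grid))

  out <- list()
  for (org in organs) for (r in replicates) for (as_ in assays) {
    row <- which(grid$organ == org & grid$replicate == r & grid$assay == as_)
    if (!length(row))
      stop("organ/replicate outside the parameter grid: ", org, " rep ", r)
    set.seed(grid$seed[row])
    if (as_ %in% c("mRNA", "input")) {
      fr <- .draw_fragments(depth, params, L, w, te_idx, te_win)
    } else {
      kept <- list(ti = integer(), fs = integer(), fe = integer())
      rate <- 0.1
      n_kept <- 0L
      while (n_kept < depth) {
        m <- min(5e6, ceiling((depth - n_kept) / rate * 1.3) + 1000)
        cand <- .draw_fragments(m, params, L, w, te_idx, te_win)
        fr_abs <- IRanges::IRanges(A[cand$ti] + cand$fs + 1L,
                                   A[cand$ti] + cand$fe)
        covers <- IRanges::overlapsAny(fr_abs, site_abs)
        mcol <- match(org, colnames(meth))
        p <- ifelse(covers, params$p_specific * meth[cand$ti, mcol],
                    params$p_nonspecific)
        keep <- stats::runif(m) < p
        kept$ti <- c(kept$ti, cand$ti[keep])
        kept$fs <- c(kept$fs, cand$fs[keep])
        kept$fe <- c(kept$fe, cand$fe[keep])
        n_kept <- length(kept$ti)
        rate <- max(mean(keep), 1e-4)
      }
      fr <- lapply(kept, function(x) x[seq_len(depth)])
    }
    ## transcript -> genomic coordinates
    g <- .frag_to_genomic(models, fr$ti, fr$fs, fr$fe)
    gr <- GenomicRanges::GRanges(models$tx$chrom[fr$ti],
                                 IRanges::IRanges(g$gs + 1L, g$ge),
                                 strand = "*")
    out[[paste0(org, "_rep", r, "_", as_)]] <-
      fragment_library(gr, org, r, as_, total_mapped = depth)
  }
  out
}

## vectorized transcript-interval -> genomic-span conversion
.frag_to_genomic <- function(models, ti, fs, fe) {
  tx <- models$tx
  ex <- models$exons
  first <- !duplicated(ex$transcript_id)
  m1 <- match(tx$transcript_id, ex$transcript_id[first])
  e1s <- ex$start[first][m1]
  e1len <- (ex$end - ex$start)[first][m1]
  second <- which(duplicated(ex$transcript_id))
  e2s <- rep(NA_integer_, nrow(tx))
  e2s[match(ex$transcript_id[second], tx$transcript_id)] <- ex$start[second]

  L <- tx$tx_len[ti]
  neg <- tx$strand[ti] == "-"
  ps <- ifelse(neg, L - fe, fs)
  pe <- ifelse(neg, L - fs, fe)
  map <- function(p) {
    one <- p < e1len[ti] | is.na(e2s[ti])
    ifelse(one, e1s[ti] + p, e2s[ti] + (p - e1len[ti]))
  }
  gs <- map(ps)
  ge <- map(pe - 1L) + 1L
  list(gs = as.integer(gs), ge = as.integer(ge))
}

#' Write a simulated dataset to disk
#'
#' FASTA genome, GFF3 annotation, one BED per library, and the truth tables
#' as TSV — the on-disk form a real experiment would arrive in.
#'
#' @param reference output of \code{\link{generate_reference}}.
#' @param libraries output of \code{\link{simulate_libraries}}.
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(reference, libraries, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(reference$genome, file.path(dir, "genome.fa"))
  write_annotation(reference$models, file.path(dir, "annotation.gff3"))
  for (nm in names(libraries))
    write_fragments(libraries[[nm]], file.path(dir, paste0(nm, ".bed")))
  write_table(reference$truth$transcripts, file.path(dir, "truth_transcripts.tsv"))
  write_table(reference$truth$sites, file.path(dir, "truth_sites.tsv"))
  write_table(reference$truth$meth_levels, file.path(dir, "truth_meth_levels.tsv"))
  invisible(dir)
}
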