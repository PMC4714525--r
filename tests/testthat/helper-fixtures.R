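## Hand-built fixtures and cached simulations shared across test files.

# two-exon plus-strand model: exons (0,100)+(200,300), CDS genomic (50,250)
two_exon_model <- function() {
  transcript_models(
    data.frame(transcript_id = "tx1", chrom = "chr1", strand = "+",
               biotype = "mRNA", cds_gstart = 50L, cds_gend = 250L),
    data.frame(transcript_id = "tx1", chrom = "chr1",
               start = c(0L, 200L), end = c(100L, 300L)))
}

single_exon_model <- function(strand = "+", len = 300L, id = "tx1") {
  transcript_models(
    data.frame(transcript_id = id, chrom = "chr1", strand = strand,
               biotype = "mRNA"),
    data.frame(transcript_id = id, chrom = "chr1", start = 0L, end = len))
}

make_lib <- function(starts, ends, chrom = "chr1", organ = "leaves",
                     replicate = 1, assay = "m6A") {
  gr <- GenomicRanges::GRanges(rep_len(chrom, length(starts)),
                               IRanges::IRanges(starts + 1L, ends))
  fragment_library(gr, organ, replicate, assay)
}

# minimal quant-record rows for the classification helpers
quant_row <- function(id, mfpkm, fpkm, m6a_count = 10, mrna_count = 10,
                      organ = "leaves", replicate = 1) {
  data.frame(transcript_id = id, organ = organ, replicate = replicate,
             mrna_count = mrna_count, m6a_count = m6a_count, fpkm = fpkm,
             covered_length = ifelse(m6a_count > 0, 150L, 0L),
             mfpkm = mfpkm,
             peak_count = ifelse(m6a_count > 0, 1L, 0L),
             stringsAsFactors = FALSE)
}

## simulations are expensive; build each scenario once per test run
.sim_cache <- new.env(parent = emptyenv())
.cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# default preset, two organs (leaves vs roots), one replicate: drives the
# extent-recovery and differential-recovery checks
sim_recovery <- function() .cached("recovery", {
  p <- sim_params(seed = 101, organs = c("leaves", "roots"), replicates = 1)
  ref <- generate_reference(p)
  libs <- simulate_libraries(ref, p, assays = c("m6A", "mRNA"))
  list(p = p, ref = ref, libs = libs,
       q_leaves = quantify(libs$leaves_rep1_m6A, libs$leaves_rep1_mRNA,
                           ref$models),
       q_roots = quantify(libs$roots_rep1_m6A, libs$roots_rep1_mRNA,
                          ref$models))
})

# default preset with no planted differences: the differential null
sim_null <- function() .cached("null", {
  p <- sim_params(seed = 202, organs = c("leaves", "roots"), replicates = 1,
                  dm_fraction = 0)
  ref <- generate_reference(p)
  libs <- simulate_libraries(ref, p, assays = c("m6A", "mRNA"))
  list(p = p, ref = ref,
       q_leaves = quantify(libs$leaves_rep1_m6A, libs$leaves_rep1_mRNA,
                           ref$models),
       q_roots = quantify(libs$roots_rep1_m6A, libs$roots_rep1_mRNA,
                          ref$models))
})

# all sites at the stop codon; the input assay doubles as the uniform null
sim_stop <- function() .cached("stop", {
  p <- sim_params(n_transcripts = 300, depth = 1e5, seed = 303,
                  organs = "leaves", replicates = 1,
                  placement = c(stop = 1, cds = 0, five = 0))
  ref <- generate_reference(p)
  libs <- simulate_libraries(ref, p, assays = c("m6A", "input"))
  list(p = p, ref = ref, libs = libs)
})

# motif-recovery scenario: AAACT planted at 40%, background capture off; the
# transcript count keeps the peak pool well above top_n so ranking excludes
# shallow peaks whose summits wander from the site
sim_motif <- function() .cached("motif", {
  w <- stats::setNames(rep(0.6 / 11, 12), names(sim_params()$motif_weights))
  w["AAACT"] <- 0.4
  p <- sim_params(n_transcripts = 800, depth = 1.5e5, seed = 404,
                  organs = "leaves", replicates = 1,
                  p_nonspecific = 0, motif_weights = w)
  ref <- generate_reference(p)
  libs <- simulate_libraries(ref, p, assays = "m6A")
  list(p = p, ref = ref, lib = libs$leaves_rep1_m6A)
})
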