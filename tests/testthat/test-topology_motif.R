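test_that("peak extraction matches hand-built depth profiles", {
  models <- single_exon_model(len = 500L)
  # one fragment: one peak spanning it, height 1
  pk <- call_peaks(make_lib(0L, 100L), models)
  expect_equal(pk[, c("start", "end", "summit", "height")],
               data.frame(start = 0L, end = 100L, summit = 0L, height = 1L))
  # disjoint covered runs split into two peaks
  pk <- call_peaks(make_lib(c(0L, 300L), c(100L, 400L)), models)
  expect_equal(nrow(pk), 2L)
  # nested fragments: one run, summit at the leftmost deepest base
  pk <- call_peaks(make_lib(c(0L, 40L), c(100L, 60L)), models)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$summit, 40L)
  expect_equal(pk$height, 2L)
})

test_that("peak spans partition covered bases for random fragment sets", {
  set.seed(41)
  n_tx <- 1000L
  tx <- data.frame(transcript_id = sprintf("t%04d", 1:n_tx), chrom = "chr1",
                   strand = "+", biotype = "mRNA")
  starts <- (0:(n_tx - 1)) * 600L
  models <- transcript_models(tx, data.frame(
    transcript_id = tx$transcript_id, chrom = "chr1",
    start = starts, end = starts + 500L))
  # a random fragment set per transcript
  nf <- sample(1:12, n_tx, replace = TRUE)
  ti <- rep(1:n_tx, nf)
  fs <- sample(0:400, length(ti), replace = TRUE)
  fe <- fs + sample(10:100, length(ti), replace = TRUE)
  lib <- make_lib(starts[ti] + fs, starts[ti] + pmin(fe, 500L))
  pk <- call_peaks(lib, models)
  spans <- tapply(pk$end - pk$start, pk$transcript_id, sum)
  pr <- project_fragments(lib$fragments, models)
  cl <- vapply(split(pr, pr$transcript_id),
               function(d) covered_length(d$start, d$end), numeric(1))
  expect_equal(as.numeric(spans[names(cl)]), as.numeric(cl))
})

test_that("metagene profile normalizes, handles zero coverage, finds the stop peak", {
  st <- sim_stop()
  prof <- metagene_profile(st$libs$leaves_rep1_m6A, st$ref$models)
  expect_length(prof$bins, 60L)
  expect_true(all(prof$bins >= 0))
  amax <- which.max(prof$bins) - 1L    # bins reported 0-based, 0 = TSS end
  expect_gte(amax, 49L)
  expect_lte(amax, 59L)
  # the un-captured input pool is uniform along transcripts
  unif <- metagene_profile(st$libs$leaves_rep1_input, st$ref$models)
  expect_lt(stats::sd(unif$bins) / mean(unif$bins), 0.05)
  # zero coverage -> all-zero profile
  z <- metagene_profile(make_lib(integer(0), integer(0)),
                        single_exon_model(len = 600L))
  expect_equal(z$bins, rep(0, 60))
})

test_that("profile comparison is an ANOVA over bins with degenerate guard", {
  st <- sim_stop()
  prof <- metagene_profile(st$libs$leaves_rep1_m6A, st$ref$models)
  ident <- compare_profiles(list(prof, prof, prof))
  expect_equal(ident$p_value, 1)
  shifted <- prof
  shifted$bins <- rev(prof$bins) * 3 + 5
  expect_lt(compare_profiles(list(prof, shifted))$p_value, 0.05)
  flat <- prof
  flat$bins <- rep(1, 60)
  deg <- compare_profiles(list(flat, flat))
  expect_equal(deg$p_value, 1)
  expect_true(deg$degenerate)
  expect_error(compare_profiles(list(prof)), "at least 2")
})

test_that("topology typing follows stop-region dominance", {
  tx <- data.frame(transcript_id = c("t1", "t2"), chrom = "chr1",
                   strand = "+", biotype = "mRNA",
                   cds_gstart = c(100L, 1100L), cds_gend = c(800L, 1800L))
  starts <- c(0L, 1000L)
  models <- transcript_models(tx, data.frame(
    transcript_id = c("t1", "t2"), chrom = "chr1",
    start = starts, end = starts + 1000L))
  # t1: single peak at the stop codon, nothing in the CDS -> Type1
  # t2: equal-height peaks in CDS and stop region -> Type2 (ratio 1 < 2)
  lib <- make_lib(c(750L, 1750L, 1300L), c(850L, 1850L, 1400L))
  topo <- classify_topology(call_peaks(lib, models), models)
  expect_equal(topo$type, c("Type1", "Type2"))
  expect_equal(topo$dominance_ratio, c(Inf, 1))
})

test_that("planted topology fractions are recovered within ten points", {
  rec <- sim_recovery()
  pks <- call_peaks(rec$libs$leaves_rep1_m6A, rec$ref$models)
  topo <- classify_topology(pks, rec$ref$models)
  tr <- rec$ref$truth$transcripts
  m <- match(topo$transcript_id, tr$transcript_id)
  ok <- !is.na(topo$type) & !is.na(tr$topology[m])
  planted <- mean(tr$topology[m][ok] == "Type1")
  called <- mean(topo$type[ok] == "Type1")
  expect_lt(abs(called - planted) * 100, 10)
})

test_that("motif windows match the consensus where and only where planted", {
  # one transcript whose only RRACH instance sits at the planted site
  tx <- single_exon_model(len = 200L)
  seq <- paste(rep("C", 200), collapse = "")
  substr(seq, 99, 103) <- "AAACT"               # 0-based site at 100
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  lib <- make_lib(c(60L, 70L), c(160L, 170L))
  pk <- call_peaks(lib, tx)
  mt <- motif_table(pk, genome, tx, top_n = 10, window = 100)
  expect_equal(mt$fraction_with_consensus, 100)
  expect_equal(mt$motifs$motif, "AAACT")
  expect_equal(mt$motifs$motif_rna, "AAACU")
  expect_equal(mt$motifs$freq, 100)
  # an all-C/G window has no consensus
  gcg <- Biostrings::DNAStringSet(c(chr1 = paste(rep("G", 200), collapse = "")))
  mt0 <- motif_table(pk, gcg, tx, top_n = 10)
  expect_equal(mt0$fraction_with_consensus, 0)
  expect_equal(nrow(mt0$motifs), 0L)
})

test_that("planted motif frequencies are recovered from top peaks", {
  mo <- sim_motif()
  pk <- call_peaks(mo$lib, mo$ref$models)
  mt <- motif_table(pk, mo$ref$genome, mo$ref$models, top_n = 500)
  expect_equal(mt$n_peaks_examined, 500L)
  expect_equal(mt$fraction_with_consensus, 100)
  aaact <- mt$motifs$freq[mt$motifs$motif == "AAACT"]
  expect_lt(abs(aaact - 40), 5)
  expect_equal(sum(mt$motifs$freq), 100)
})
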